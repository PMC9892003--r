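#' Model configuration for the association fit
#'
#' @param reference_category Outcome category used as the log-odds reference;
#'   defaults to `"none"` / `"not-in-polysome"` when present, otherwise the
#'   most abundant category.
#' @param ci_level Confidence level for predicted-probability intervals.
#' @param max_iterations Outer optimizer iteration cap.
#' @param convergence_tolerance Relative tolerance of the outer optimizer.
#' @param estimation_method `"laplace"` (any number of outcome categories) or
#'   `"agq"` (adaptive Gauss-Hermite, two outcome categories).
#' @param n_quadrature Number of quadrature nodes for `"agq"`.
#' @param fix_random_variance Optionally fix the random-intercept standard
#'   deviation (e.g. 0 for the pooled multinomial logit limit); NULL
#'   estimates it.
#' @return A `model_config` list.
#' @export
model_config <- function(reference_category = NULL, ci_level = 0.95,
                         max_iterations = 500, convergence_tolerance = 1e-10,
                         estimation_method = c("laplace", "agq"),
                         n_quadrature = 15, fix_random_variance = NULL) {
  stopifnot(ci_level > 0, ci_level < 1)
  structure(list(reference_category = reference_category,
                 ci_level = ci_level,
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 estimation_method = match.arg(estimation_method),
                 n_quadrature = as.integer(n_quadrature),
                 fix_random_variance = fix_random_variance),
            class = "model_config")
}

pick_reference <- function(levels, counts, requested) {
  if (!is.null(requested)) {
    if (!requested %in% levels) stop("reference category '", requested,
                                     "' not among outcomes")
    return(requested)
  }
  conventional <- c("none", "not-in-polysome", "not_in_polysome", "monosome",
                    "not")
  hit <- intersect(conventional, levels)
  if (length(hit)) hit[1] else levels[which.max(counts)]
}

# delta-method CI for softmax probabilities on the logit scale
softmax_ci <- function(beta_s, cov_s, ci_level) {
  K1 <- length(beta_s)
  expb <- exp(beta_s)
  D <- 1 + sum(expb)
  p <- c(1, expb) / D
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  lo <- hi <- numeric(K1 + 1)
  for (k in 0:K1) {
    pk <- p[k + 1]
    # d logit(p_k) / d beta_l
    grad <- vapply(seq_len(K1), function(l) {
      pl <- p[l + 1]
      if (l == k) 1 else -pl / (1 - pk)
    }, numeric(1))
    v <- as.numeric(t(grad) %*% cov_s %*% grad)
    v <- max(v, 0)
    lg <- stats::qlogis(pk)
    lo[k + 1] <- stats::plogis(lg - z * sqrt(v))
    hi[k + 1] <- stats::plogis(lg + z * sqrt(v))
  }
  list(p = p, lo = lo, hi = hi)
}

#' Fit the multinomial mixed-effects logistic regression
#'
#' Fits log-odds(outcome = k vs reference | state s, tomogram t) =
#' beta\[k, s\] + u\[k, t\], with independent Gaussian random intercepts
#' u\[k, t\] ~ N(0, sigma_k^2) per tomogram and non-reference category, so
#' that per-tomogram abundance variation from sample and imaging differences
#' does not masquerade as a state effect. The marginal likelihood is
#' maximized with a per-tomogram Laplace approximation (adaptive
#' Gauss-Hermite available for two outcome categories). Predicted
#' probabilities are conditional on a typical tomogram (u = 0), with
#' delta-method confidence intervals computed on the log-odds scale and
#' back-transformed. All pairwise state contrasts per non-reference outcome
#' are tested with two-sided Wald tests and Hochberg-adjusted.
#'
#' @param observations data.frame with columns `tomogram_id`, `state`,
#'   `outcome` (one row per ribosome/event).
#' @param config A [model_config()].
#' @return An `association_fit`: coefficients (matrix, non-reference outcome
#'   by state), their covariance, random-intercept SDs, the
#'   predicted-probability table, the contrast table, convergence
#'   information and separation flags.
#' @export
fit_association_model <- function(observations, config = model_config()) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("tomogram_id", "state", "outcome") %in% names(obs)))
  obs$tomogram_id <- as.character(obs$tomogram_id)
  obs$state <- as.character(obs$state)
  obs$outcome <- as.character(obs$outcome)
  out_levels <- sort(unique(obs$outcome))
  if (length(out_levels) < 2) stop("need at least 2 outcome categories")
  toms <- sort(unique(obs$tomogram_id))
  est_sigma <- is.null(config$fix_random_variance)
  if (length(toms) < 2 && est_sigma)
    stop("need at least 2 tomograms to estimate the random-intercept variance")
  states <- sort(unique(obs$state))
  out_counts <- table(factor(obs$outcome, levels = out_levels))
  ref <- pick_reference(out_levels, as.integer(out_counts),
                        config$reference_category)
  out_levels <- c(ref, setdiff(out_levels, ref))
  K <- length(out_levels); K1 <- K - 1L
  S <- length(states); Tn <- length(toms)
  counts <- table(factor(obs$tomogram_id, levels = toms),
                  factor(obs$state, levels = states),
                  factor(obs$outcome, levels = out_levels))
  counts <- array(as.integer(counts), dim = dim(counts))
  # separation: a state with every observation in a single outcome category
  pooled <- apply(counts, c(2, 3), sum)
  if (any(rowSums(pooled) == 0)) stop("every state must be observed at least once")
  separated <- states[apply(pooled, 1, function(r) sum(r > 0) == 1)]
  if (length(separated))
    warning("complete separation for state(s) ",
            paste(separated, collapse = ", "),
            "; coefficients diverge and standard errors are inflated")
  # starting values: pooled empirical log-odds with a half-count guard
  beta0 <- t(log((pooled[, -1, drop = FALSE] + 0.5) / (pooled[, 1] + 0.5)))
  binary <- K == 2
  method <- config$estimation_method
  if (method == "agq" && !binary) {
    message("adaptive Gauss-Hermite is implemented for 2 outcome categories; ",
            "using the Laplace approximation")
    method <- "laplace"
  }
  gh <- if (method == "agq") gh_rule(config$n_quadrature) else NULL
  nagq <- if (method == "agq") config$n_quadrature else 1L
  if (binary) {
    Y <- matrix(counts[, , 2], Tn, S)
    N <- matrix(counts[, , 1] + counts[, , 2], Tn, S)
    fn <- function(theta) mml_negll_binary(theta, Y, N,
                                           fixed_sigma = config$fix_random_variance,
                                           nagq = nagq, gh = gh)
  } else {
    fn <- function(theta) mml_negll_laplace(theta, counts, K, S,
                                            fixed_sigma = config$fix_random_variance)
  }
  theta0 <- as.numeric(beta0)
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  if (est_sigma) {
    theta0 <- c(theta0, rep(log(0.5), K1))
    lower <- c(lower, rep(log(1e-4), K1))
    upper <- c(upper, rep(log(25), K1))
  }
  opt <- stats::nlminb(theta0, fn, lower = lower, upper = upper,
                       control = list(iter.max = config$max_iterations,
                                      eval.max = 4 * config$max_iterations,
                                      rel.tol = config$convergence_tolerance))
  msg <- opt$message %||% ""
  # "singular convergence" arises when a variance sits at its boundary;
  # the fixed-effect estimates remain valid, as in other mixed-model fitters
  ok <- opt$convergence == 0 ||
    grepl("relative convergence|both X- and relative|singular convergence",
          msg) ||
    (grepl("false convergence", msg) && length(separated) > 0)
  if (!ok)
    stop("association model did not converge after ", opt$iterations,
         " iterations (", msg, ")")
  theta_hat <- opt$par
  beta <- matrix(theta_hat[seq_len(K1 * S)], K1, S,
                 dimnames = list(out_levels[-1], states))
  sigma <- if (est_sigma) exp(theta_hat[K1 * S + seq_len(K1)])
           else rep(config$fix_random_variance, K1)
  names(sigma) <- out_levels[-1]
  H <- stats::optimHess(theta_hat, fn)
  full_cov <- sym_inverse(H)
  bidx <- seq_len(K1 * S)
  cov_beta <- full_cov[bidx, bidx, drop = FALSE]
  cn <- as.vector(outer(out_levels[-1], states, function(k, s) paste(k, s, sep = "|")))
  dimnames(cov_beta) <- list(cn, cn)
  # predicted probabilities per state with delta-method CIs
  pred <- do.call(rbind, lapply(seq_len(S), function(s) {
    idx <- (s - 1L) * K1 + seq_len(K1)
    ci <- softmax_ci(beta[, s], cov_beta[idx, idx, drop = FALSE],
                     config$ci_level)
    data.frame(state = states[s], outcome = out_levels,
               mean = ci$p, ci_low = ci$lo, ci_high = ci$hi,
               stringsAsFactors = FALSE)
  }))
  rownames(pred) <- NULL
  fit <- structure(list(
    coefficients = beta, covariance = cov_beta,
    random_intercept_sd = sigma,
    predicted_probabilities = pred,
    outcome_levels = out_levels, states = states, tomograms = toms,
    reference_category = ref,
    logLik = -opt$objective,
    convergence = opt$convergence, iterations = opt$iterations,
    message = opt$message,
    separated_states = separated,
    estimation_method = method,
    config = config, counts = counts), class = "association_fit")
  if (S >= 2) {
    pairs <- utils::combn(states, 2)
    contr <- do.call(rbind, lapply(out_levels[-1], function(k) {
      data.frame(state_a = pairs[1, ], state_b = pairs[2, ], outcome = k,
                 stringsAsFactors = FALSE)
    }))
    wc <- wald_contrast(fit, contr)
    wc$p_adjusted <- hochberg_adjust(wc$p_raw)
    fit$contrasts <- wc
  } else {
    fit$contrasts <- NULL
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf(paste0("multinomial mixed-effects logistic regression (%s)\n",
                     "  %d observations, %d tomograms, %d states, ",
                     "%d outcome categories (reference '%s')\n"),
              x$estimation_method, sum(x$counts), length(x$tomograms),
              length(x$states), length(x$outcome_levels), x$reference_category))
  cat("  random-intercept sd:",
      paste(sprintf("%s %.3f", names(x$random_intercept_sd),
                    x$random_intercept_sd), collapse = ", "), "\n")
  print(x$predicted_probabilities, digits = 3)
  invisible(x)
}

#' Two-sided Wald tests of state contrasts
#'
#' Tests beta\[outcome, state_a\] - beta\[outcome, state_b\] = 0 using the
#' fitted coefficient covariance and the normal reference distribution.
#'
#' @param fit An `association_fit`.
#' @param contrasts data.frame with columns `state_a`, `state_b`, `outcome`.
#' @return The contrast table extended with `estimate`, `se`, `z`, `p_raw`.
#' @export
wald_contrast <- function(fit, contrasts) {
  stopifnot(inherits(fit, "association_fit"))
  ct <- as.data.frame(contrasts)
  res <- lapply(seq_len(nrow(ct)), function(r) {
    a <- ct$state_a[r]; b <- ct$state_b[r]; k <- ct$outcome[r]
    if (!a %in% fit$states) stop("unknown state '", a, "'")
    if (!b %in% fit$states) stop("unknown state '", b, "'")
    if (!k %in% fit$outcome_levels[-1])
      stop("outcome '", k, "' is not a non-reference category")
    ka <- paste(k, a, sep = "|"); kb <- paste(k, b, sep = "|")
    est <- fit$coefficients[k, a] - fit$coefficients[k, b]
    v <- fit$covariance[ka, ka] + fit$covariance[kb, kb] -
      2 * fit$covariance[ka, kb]
    se <- sqrt(max(v, 0))
    z <- if (est == 0 && se == 0) 0 else est / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(estimate = est, se = se, z = z, p_raw = p)
  })
  cbind(ct, do.call(rbind, res))
}

#' Hochberg step-up multiple-testing adjustment
#'
#' Controls the family-wise error rate under nonnegative dependence;
#' adjusted p-values are returned in the input order and never fall below
#' the raw values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
hochberg_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Fractional abundance of each category
#'
#' The random-association probability of a category is its fractional
#' abundance in the dataset: counts / total.
#'
#' @param table A [particle_table()] (or any data.frame).
#' @param field Column whose categories are counted (e.g. `"state_label"`).
#' @return Named numeric vector of fractions summing to 1.
#' @export
abundance_table <- function(table, field = "state_label") {
  stopifnot(nrow(table) > 0)
  tab <- table(table[[field]])
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Fold increase over random association
#'
#' Divides the modelled mean probability and its confidence-interval bounds
#' by the random-association probability (the outcome category's fractional
#' abundance); a fold of 1 means no enrichment. Intended for display on a
#' logarithmic axis.
#'
#' @param fit An `association_fit`.
#' @param abundances Named per-outcome fractional abundances (sum to 1, all
#'   positive). Categories absent from the fit are ignored.
#' @return data.frame with `state`, `outcome`, `fold`, `fold_ci_low`,
#'   `fold_ci_high`.
#' @export
fold_increase <- function(fit, abundances) {
  stopifnot(inherits(fit, "association_fit"))
  pred <- fit$predicted_probabilities
  need <- unique(pred$outcome)
  for (k in need) {
    if (!k %in% names(abundances))
      stop("no abundance supplied for outcome category '", k, "'")
    if (abundances[[k]] <= 0)
      stop("zero abundance for outcome category '", k, "'")
  }
  ab <- as.numeric(abundances[pred$outcome])
  data.frame(state = pred$state, outcome = pred$outcome,
             fold = pred$mean / ab,
             fold_ci_low = pred$ci_low / ab,
             fold_ci_high = pred$ci_high / ab,
             stringsAsFactors = FALSE)
}

#' Build association observations from linked particles
#'
#' Turns a particle table plus confirmed polysome links into the observation
#' table consumed by [fit_association_model()].
#'
#' Outcome modes:
#' * `"membership"` — binary: `"in-polysome"` if the particle participates in
#'   at least one confirmed link (either direction), else `"none"`.
#' * `"leading_state"` — the state label of the particle's confirmed leading
#'   (downstream) neighbour, or `"none"`.
#' * `"trailing_state"` — likewise for the upstream neighbour.
#'
#' @param table A [particle_table()].
#' @param links A `polysome_links` object.
#' @param outcome Outcome mode (above).
#' @param state_from Predictor column (`"state_label"` or
#'   `"population_label"`).
#' @return data.frame with `tomogram_id`, `state`, `outcome`.
#' @export
association_observations <- function(table, links,
                                     outcome = c("membership", "leading_state",
                                                 "trailing_state"),
                                     state_from = "state_label") {
  outcome <- match.arg(outcome)
  key <- paste(table$tomogram_id, table$particle_id, sep = "\r")
  e <- links$edges
  if (outcome == "membership") {
    mkey <- paste(links$members$tomogram_id, links$members$particle_id,
                  sep = "\r")
    out <- ifelse(key %in% mkey, "in-polysome", "none")
  } else if (outcome == "leading_state") {
    # particle is the trailing end of the edge; neighbour is its leader
    ekey <- paste(e$tomogram_id, e$trailing_id, sep = "\r")
    nkey <- paste(e$tomogram_id, e$leading_id, sep = "\r")
    idx <- match(key, ekey)
    out <- ifelse(is.na(idx), "none",
                  table[[state_from]][match(nkey[idx], key)])
  } else {
    ekey <- paste(e$tomogram_id, e$leading_id, sep = "\r")
    nkey <- paste(e$tomogram_id, e$trailing_id, sep = "\r")
    idx <- match(key, ekey)
    out <- ifelse(is.na(idx), "none",
                  table[[state_from]][match(nkey[idx], key)])
  }
  data.frame(tomogram_id = table$tomogram_id,
             state = table[[state_from]],
             outcome = out, stringsAsFactors = FALSE)
}

#' Dot-and-error-bar association plot
#'
#' Modelled means with confidence intervals per state, a horizontal
#' random-association reference line, and the per-tomogram event frequencies
#' as small scattered points.
#'
#' @param fit An `association_fit`.
#' @param frequencies Optional [per_tomogram_frequencies()] table (columns
#'   `group`, `frequency`).
#' @param outcome Which outcome category to plot (default: first
#'   non-reference).
#' @param reference Optional random-association probability for the
#'   reference line.
#' @return A ggplot object.
#' @export
plot_association <- function(fit, frequencies = NULL, outcome = NULL,
                             reference = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_association requires the ggplot2 package")
  outcome <- outcome %||% fit$outcome_levels[2]
  pred <- fit$predicted_probabilities
  pred <- pred[pred$outcome == outcome, , drop = FALSE]
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = state, y = mean))
  if (!is.null(frequencies)) {
    p <- p + ggplot2::geom_jitter(
      data = data.frame(state = frequencies$group, mean = frequencies$frequency),
      width = 0.15, size = 0.5, alpha = 0.4, colour = "grey50")
  }
  if (!is.null(reference))
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dashed")
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
    ggplot2::labs(x = NULL, y = paste0("P(", outcome, ")")) +
    ggplot2::theme_classic()
}
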
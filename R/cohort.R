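#' Generate a synthetic patient cohort
#'
#' Emulates the statistical structure of a pre/post pulmonary-valve-
#' implantation study population: per patient, a synthetic PA tree, a pair of
#' inflow waveforms (a regurgitant pre-implantation state and a competent
#' post-implantation state) and clinical covariates. Default regurgitant
#' fractions are drawn around the reported population means (pre 44.2%, post
#' 14.5%); every patient's pre-state regurgitant fraction strictly exceeds
#' the post-state one. Fully deterministic given `seed`.
#'
#' When `effect_config` is supplied, the cohort additionally carries a
#' regression bench: standard-normal covariates `x1..xk`, a response
#' `y = X beta + N(0, sigma^2)` and the true coefficients, for
#' recovery tests of [screened_regression()].
#'
#' @param n_patients Number of patients (>= 2).
#' @param seed Integer seed.
#' @param effect_config Optional list with `betas` (numeric vector) and
#'   `sigma` (noise SD, >= 0); `n` overrides the number of regression rows
#'   (default `n_patients`).
#' @param pr_pre_mean,pr_pre_sd,pr_post_mean,pr_post_sd Regurgitant-fraction
#'   distribution of the two states.
#' @param n_outlets_per_side,radius_dispersion Tree-generator settings.
#' @param n_samples Waveform samples per cycle.
#' @return Object of class `cohort_table`: `patients` (list of per-patient
#'   records with `id`, `tree`, `pre`, `post` waveforms, `pr_pre`, `pr_post`,
#'   `covariates`), `covariates` (`data.frame`), `regression` (or NULL),
#'   `seed`.
#' @export
generate_cohort <- function(n_patients = 9L, seed = 1L, effect_config = NULL,
                            pr_pre_mean = 0.442, pr_pre_sd = 0.05,
                            pr_post_mean = 0.145, pr_post_sd = 0.04,
                            n_outlets_per_side = 10L, radius_dispersion = 0.3,
                            n_samples = 256L) {
  if (n_patients < 2L) stop("`n_patients` must be >= 2 (statistics need at least 2)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  n <- as.integer(n_patients)
  cov <- data.frame(
    patient = seq_len(n),
    sex = factor(sample(c("F", "M"), n, replace = TRUE, prob = c(2 / 3, 1 / 3))),
    age_at_surgery_months = clip(stats::rlnorm(n, log(10), 0.7), 1, 60),
    age_at_ppvi_years = clip(stats::rnorm(n, 23, 3.5), 12, 40),
    mean_pa_pressure_mmhg = clip(stats::rnorm(n, 13, 2.5), 7, 22),
    stroke_volume_ml = clip(stats::rnorm(n, 75, 10), 45, 110),
    period_s = clip(stats::rnorm(n, 0.9, 0.05), 0.65, 1.15),
    mpa_radius_cm = clip(stats::rnorm(n, 1.2, 0.12), 0.85, 1.6),
    rpa_fraction_pre = clip(stats::rnorm(n, 0.614, 0.03), 0.45, 0.75),
    rpa_fraction_post = clip(stats::rnorm(n, 0.594, 0.03), 0.45, 0.75)
  )
  pr_pre <- clip(stats::rnorm(n, pr_pre_mean, pr_pre_sd), 0.25, 0.65)
  pr_post <- clip(stats::rnorm(n, pr_post_mean, pr_post_sd), 0.03, 0.30)
  pr_post <- pmin(pr_post, pr_pre - 0.05)   # pre-state PR strictly larger
  cov$pr_pre <- pr_pre
  cov$pr_post <- pr_post

  patients <- lapply(seq_len(n), function(i) {
    tree <- generate_pa_tree(n_outlets_per_side,
                             mpa_radius = cov$mpa_radius_cm[i],
                             radius_dispersion = radius_dispersion,
                             seed = seed + 7919L * i)
    list(
      id = i, tree = tree,
      pre = generate_inflow_waveform(cov$stroke_volume_ml[i], cov$period_s[i],
                                     pr_target = pr_pre[i],
                                     n_samples = n_samples),
      post = generate_inflow_waveform(cov$stroke_volume_ml[i], cov$period_s[i],
                                      pr_target = pr_post[i],
                                      n_samples = n_samples),
      pr_pre = pr_pre[i], pr_post = pr_post[i],
      covariates = cov[i, ]
    )
  })

  regression <- NULL
  if (!is.null(effect_config)) {
    betas <- effect_config$betas
    sigma <- if (is.null(effect_config$sigma)) 1 else effect_config$sigma
    nr <- if (is.null(effect_config$n)) n else as.integer(effect_config$n)
    k <- length(betas)
    X <- matrix(stats::rnorm(nr * k), nr, k,
                dimnames = list(NULL, paste0("x", seq_len(k))))
    y <- as.vector(X %*% betas) + stats::rnorm(nr, 0, sigma)
    regression <- list(design = as.data.frame(X), response = y, betas = betas,
                       sigma = sigma)
  }

  structure(list(patients = patients, covariates = cov,
                 regression = regression, seed = seed),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d patients (seed %d); PR fraction pre %.3f +/- %.3f, post %.3f +/- %.3f\n",
    length(x$patients), x$seed,
    mean(x$covariates$pr_pre), stats::sd(x$covariates$pr_pre),
    mean(x$covariates$pr_post), stats::sd(x$covariates$pr_post)))
  invisible(x)
}
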
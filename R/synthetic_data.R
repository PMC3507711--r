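# Seeded generators standing in for the non-deposited hospital cohort:
# (a) 2-D geometric imbalance scenarios (coherent vs sparse minority),
# (b) a full-shape PCA cohort with hourly usage series and a planted,
#     weight-defined continuous dose target.

#' Generate a 2-D imbalanced scenario
#'
#' Two numeric attributes and a binary class. `kind = "coherent"` draws the
#' minority from a compact Gaussian blob disjoint from the majority blob, so
#' the class boundary is clear despite the imbalance. `kind = "sparse"`
#' scatters the minority uniformly inside the majority's support, the
#' geometry in which random over/under-sampling fails and dirty-example
#' cleaning is designed to help.
#'
#' @param kind `"coherent"` or `"sparse"`.
#' @param n_majority,n_minority Class sizes (`n_minority <= n_majority`).
#' @param minority_spread Positive multiplier on the coherent minority blob's
#'   standard deviation.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `patient_tbl` with attributes `x1`, `x2` and target `class`
#'   (labels `majority`, `minority`).
#' @export
gen_scenario2d <- function(kind = c("coherent", "sparse"), n_majority = 81L,
                           n_minority = 19L, minority_spread = 1,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_majority >= 1, n_minority >= 1, n_minority <= n_majority,
    minority_spread > 0)
  set.seed(seed)
  maj <- matrix(stats::rnorm(2 * n_majority), ncol = 2)
  mino <- if (kind == "coherent") {
    matrix(stats::rnorm(2 * n_minority, mean = 5, sd = 0.5 * minority_spread),
      ncol = 2)
  } else {
    matrix(stats::runif(2 * n_minority, -2, 2) * minority_spread, ncol = 2)
  }
  xy <- rbind(maj, mino)
  data <- tibble::tibble(
    x1 = pmin(pmax(xy[, 1], -20), 20),
    x2 = pmin(pmax(xy[, 2], -20), 20),
    class = rep(c("majority", "minority"), c(n_majority, n_minority))
  )
  patient_table(data, scenario2d_schema())
}

#' Schema of the 2-D scenario tables
#' @return A [pca_schema()].
#' @export
scenario2d_schema <- function() {
  pca_schema(
    tibble::tibble(
      name = c("x1", "x2"),
      kind = "numeric",
      domain = list(c(-20, 20), c(-20, 20))
    ),
    target = list(name = "class", kind = "nominal",
      labels = c("majority", "minority"))
  )
}

# ---- PCA cohort ------------------------------------------------------------

HOURS <- 1:24
HOURLY_SERIES <- c("success_p", "failure_p", "pcadose", "contidose",
  "readjustcount", "p_timediff_mean", "p_timediff_var", "pcamode_set",
  "pcadose_set", "lockout_set", "4hrlimit_set")

hourly_names <- function(series) paste0(series, "_", HOURS, "hr")

#' Schema of the synthetic PCA cohort
#'
#' 279 descriptive attributes: 3 demographic (age, gender, weight), 7
#' biomedical (pulse, sbp, dbp, DM, HT, AMI, ASA_CLASS), 4 operation-related
#' (OP_CLASS, op_time, URGENCY, ANS_WAY), loading_dose, and 11 hourly series
#' over the first 24 h of PCA treatment (successful/failed demands, PCA and
#' continuous dose delivered, readjustment counts, demand time-gap mean and
#' variance, and the pump settings: mode, bolus dose, lockout, 4-h limit).
#' With the target attribute the table has 280 columns.
#'
#' @param target `"dose"` for the continuous 72-h total dose target,
#'   `"readjust"` for the binary readjustment target.
#' @return A [pca_schema()].
#' @export
cohort_schema <- function(target = c("dose", "readjust")) {
  target <- match.arg(target)
  num <- function(name, lo, hi) {
    tibble::tibble(name = name, kind = "numeric", domain = list(c(lo, hi)))
  }
  nom <- function(name, values) {
    tibble::tibble(name = name, kind = "nominal", domain = list(values))
  }
  series_block <- function(series) {
    switch(series,
      success_p = num(hourly_names(series), 0, 100),
      failure_p = num(hourly_names(series), 0, 100),
      pcadose = num(hourly_names(series), 0, 300),
      contidose = num(hourly_names(series), 0, 50),
      readjustcount = num(hourly_names(series), 0, 20),
      p_timediff_mean = num(hourly_names(series), 0, 120),
      p_timediff_var = num(hourly_names(series), 0, 1e4),
      pcamode_set = nom(hourly_names(series),
        c("PCA and continuous", "PCA only")),
      pcadose_set = num(hourly_names(series), 0, 10),
      lockout_set = num(hourly_names(series), 1, 60),
      `4hrlimit_set` = num(hourly_names(series), 0, 200)
    )
  }
  attrs <- dplyr::bind_rows(
    num("age", 0, 120), nom("gender", c("F", "M")), num("weight", 20, 250),
    num("pulse", 20, 220), num("sbp", 50, 280), num("dbp", 20, 180),
    nom("DM", c("N", "Y")), nom("HT", c("N", "Y")), nom("AMI", c("N", "Y")),
    nom("ASA_CLASS", as.character(1:6)),
    nom("OP_CLASS", as.character(1:8)), num("op_time", 5, 1200),
    nom("URGENCY", c("E", "R")),
    nom("ANS_WAY", c("SA", "GA", "LE", "NB")),
    num("loading_dose", 0, 100),
    dplyr::bind_rows(lapply(HOURLY_SERIES, series_block))
  )
  tgt <- if (target == "dose") {
    list(name = "total_dose_72h", kind = "numeric", range = c(-1e5, 1e5))
  } else {
    list(name = "readjust", kind = "nominal", labels = c("no", "yes"))
  }
  pca_schema(attrs, tgt)
}

#' Default planted dose weights
#'
#' The continuous 72-h dose target is a linear-plus-noise function of the
#' table's attributes; these weights put mass on the hourly PCA dose columns
#' (extrapolating the first 24 h of demand-driven consumption to 72 h) and
#' small demographic effects.
#'
#' @return A named numeric vector of attribute weights.
#' @export
default_dose_weights <- function() {
  w <- stats::setNames(rep(1, 24), hourly_names("pcadose"))
  c(w, age = -0.4, weight = 0.25)
}

#' Generate a synthetic PCA cohort
#'
#' Emulates the structure of an hourly PCA usage dataset: each patient gets
#' a latent consumption level (low/medium/high mixture with the given
#' proportions) driving a Poisson demand process over 24 h; delivered PCA
#' dose is bolus setting times successful demands, so the hourly-consistency
#' invariants hold by construction (`pcadose <= pcadose_set * success_p`,
#' `contidose = 0` under "PCA only" mode). The continuous 72-h dose target
#' is `sum(weights * attributes) + N(0, noise_sd)`; with the default
#' weights the latent mixture makes the dose trimodal so that
#' equal-deviation discretization recovers class sizes close to the
#' configured proportions.
#'
#' @param n_patients Number of rows (the emulated study had 1099).
#' @param consumption_class_proportions Three non-negative proportions
#'   summing to 1 (the emulated study's classes were 399/551/149, i.e.
#'   0.363/0.501/0.136).
#' @param hourly_effect_weights Named numeric vector of planted attribute
#'   weights for the dose target; defaults to [default_dose_weights()].
#'   All-zero weights give a pure-noise target with no attribute signal.
#' The three latent classes share (by construction) the same total dose
#' variance: the demand-level jitter of each class is sized to compensate
#' for the Poisson dose variance its demand level implies, since the
#' equal-deviation discretizer recovers mixture components at the planted
#' proportions only when within-component deviations match.
#'
#' @param noise_sd Standard deviation of the additive dose noise (mg).
#' @param seed Integer seed; identical configs and seeds give identical
#'   tables.
#' @return A `patient_tbl` with 279 descriptive attributes plus the
#'   continuous `total_dose_72h` target (280 columns, excluding the
#'   `.row_id` bookkeeping column).
#' @export
gen_pca_cohort <- function(n_patients = 1099L,
                           consumption_class_proportions = c(0.363, 0.501, 0.136),
                           hourly_effect_weights = default_dose_weights(),
                           noise_sd = 10,
                           seed = 1L) {
  n <- as.integer(n_patients)
  pr <- consumption_class_proportions
  stopifnot(n >= 1, length(pr) == 3, all(pr >= 0),
    abs(sum(pr) - 1) < 1e-9, noise_sd > 0)
  set.seed(seed)

  rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

  z <- sample.int(3, n, replace = TRUE, prob = pr)

  data <- tibble::tibble(
    age = round(rtrunc(n, 55, 15, 18, 95)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    weight = round(rtrunc(n, 65, 12, 35, 130), 1),
    pulse = round(rtrunc(n, 78, 12, 40, 160)),
    sbp = round(rtrunc(n, 126, 16, 70, 230)),
    dbp = round(rtrunc(n, 76, 11, 40, 140)),
    DM = sample(c("N", "Y"), n, replace = TRUE, prob = c(0.82, 0.18)),
    HT = sample(c("N", "Y"), n, replace = TRUE, prob = c(0.68, 0.32)),
    AMI = sample(c("N", "Y"), n, replace = TRUE, prob = c(0.96, 0.04)),
    ASA_CLASS = sample(as.character(1:6), n, replace = TRUE,
      prob = c(0.15, 0.45, 0.30, 0.07, 0.02, 0.01)),
    OP_CLASS = sample(as.character(1:8), n, replace = TRUE,
      prob = c(0.10, 0.20, 0.25, 0.10, 0.15, 0.10, 0.05, 0.05)),
    op_time = round(rtrunc(n, 170, 60, 20, 600)),
    URGENCY = sample(c("E", "R"), n, replace = TRUE, prob = c(0.12, 0.88)),
    ANS_WAY = sample(c("SA", "GA", "LE", "NB"), n, replace = TRUE,
      prob = c(0.15, 0.70, 0.10, 0.05)),
    loading_dose = round(stats::rgamma(n, shape = 2, scale = 1.5), 1)
  )

  bolus <- sample(c(0.5, 1, 1.5, 2), n, replace = TRUE,
    prob = c(0.05, 0.8, 0.1, 0.05))
  lockout <- sample(c(5, 6, 8, 10), n, replace = TRUE)
  mode <- sample(c("PCA and continuous", "PCA only"), n, replace = TRUE,
    prob = c(0.7, 0.3))
  conti_rate <- ifelse(mode == "PCA and continuous",
    round(1.0 * exp(stats::rnorm(n, 0, 0.25)), 2), 0)

  # Per-patient 24-h demand level (successful demands, before hourly decay).
  # Each class's level jitter compensates the Poisson variance its mean dose
  # implies, so all three classes have the same total dose variance and the
  # equal-deviation discretizer can recover the planted proportions.
  decay_sum <- sum(exp(-0.04 * (HOURS - 1)))
  level_mean <- c(3.5, 10.5, 24)[z]
  v_max <- 2.05 * 24 * decay_sum  # Poisson dose variance ceiling (b*L <= 2*24)
  level_jitter_sd <- sqrt(pmax(v_max - bolus * level_mean * decay_sum, 0)) /
    decay_sum
  level <- pmax(level_mean + stats::rnorm(n, 0, level_jitter_sd), 0.3)

  cols <- list()
  for (h in HOURS) {
    decay <- exp(-0.04 * (h - 1))
    lam <- level / bolus * decay
    succ <- stats::rpois(n, lam)
    fail <- stats::rpois(n, 0.35 * lam)
    demands <- succ + fail
    cols[[paste0("success_p_", h, "hr")]] <- succ
    cols[[paste0("failure_p_", h, "hr")]] <- fail
    cols[[paste0("pcadose_", h, "hr")]] <- bolus * succ
    cols[[paste0("contidose_", h, "hr")]] <- conti_rate
    cols[[paste0("readjustcount_", h, "hr")]] <- stats::rpois(n, 0.04)
    cols[[paste0("p_timediff_mean_", h, "hr")]] <-
      ifelse(demands >= 2,
        pmin(round(60 / demands * exp(stats::rnorm(n, 0, 0.2)), 2), 120), 0)
    cols[[paste0("p_timediff_var_", h, "hr")]] <-
      ifelse(demands >= 2, round(stats::rgamma(n, shape = 2, scale = 60), 2), 0)
    cols[[paste0("pcamode_set_", h, "hr")]] <- mode
    cols[[paste0("pcadose_set_", h, "hr")]] <- bolus
    cols[[paste0("lockout_set_", h, "hr")]] <- lockout
    cols[[paste0("4hrlimit_set_", h, "hr")]] <- bolus * 20
  }
  hourly <- tibble::as_tibble(cols)
  # Table-1 ordering: full series blocks, hours 1..24 within each
  hourly <- hourly[, unlist(lapply(HOURLY_SERIES, hourly_names))]
  data <- dplyr::bind_cols(data, hourly)

  dose <- stats::rnorm(n, 0, noise_sd)
  if (length(hourly_effect_weights) > 0) {
    bad <- setdiff(names(hourly_effect_weights), names(data))
    if (length(bad) > 0) {
      rlang::abort(paste0("weight names not in cohort attributes: ",
        paste(bad, collapse = ", ")), class = "pcatree_generator_error")
    }
    for (nm in names(hourly_effect_weights)) {
      dose <- dose + hourly_effect_weights[[nm]] * as.numeric(data[[nm]])
    }
  }
  data$total_dose_72h <- dose
  patient_table(data, cohort_schema("dose"))
}

#' Attach a binary PCA-readjustment target to a cohort
#'
#' Replaces the continuous dose target with a binary `readjust` label drawn
#' from a logistic model on the first-24-h profile (failed demands, demand
#' time-gap variance and systolic blood pressure carry moderate positive
#' weights). The intercept is calibrated so the expected positive rate
#' equals `readjust_positive_rate`; the moderate effect sizes leave the
#' positives scattered inside the negative class's support, reproducing the
#' sparse-minority geometry in high dimension.
#'
#' @param data A cohort from [gen_pca_cohort()].
#' @param readjust_positive_rate Positive-class probability in (0, 1); the
#'   emulated study's ratio was 81:19.
#' @param seed Integer seed.
#' @return A `patient_tbl` with 279 descriptive attributes and the nominal
#'   `readjust` target (labels `no`, `yes`).
#' @export
gen_readjust_labels <- function(data, readjust_positive_rate = 0.19,
                                seed = 1L) {
  rate <- readjust_positive_rate
  if (!(rate > 0 && rate < 1)) {
    rlang::abort("readjust_positive_rate must be in (0, 1)",
      class = "pcatree_generator_error")
  }
  zscale <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  fail_sum <- rowSums(as.matrix(data[, hourly_names("failure_p")]))
  var_mean <- rowMeans(as.matrix(data[, hourly_names("p_timediff_var")]))
  eta0 <- 1.1 * zscale(fail_sum) + 0.7 * zscale(var_mean) +
    0.5 * zscale(as.numeric(data$sbp))
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - rate,
    c(-30, 30), tol = 1e-10)$root
  p <- stats::plogis(b0 + eta0)
  set.seed(seed)
  lab <- ifelse(stats::runif(nrow(data)) < p, "yes", "no")
  schema <- cohort_schema("readjust")
  out <- data[, c(".row_id", schema_attr_names(schema))]
  out$readjust <- lab
  patient_table(out, schema)
}
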
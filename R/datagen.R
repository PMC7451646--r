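#' Default variable roster for the hierarchical remission simulation
#'
#' Returns the metadata for the 26 candidate predictors used by the
#' synthetic three-level generator: 20 patient-level variables, 4
#' doctor-level variables (including the doctor identifier `DID`) and 2
#' hospital-level variables (including the hospital identifier `HID`).
#' The patient identifier `ID` is part of generated datasets but is never a
#' candidate predictor; the cluster identifiers `DID` and `HID` are
#' candidates, because cluster membership itself carries outcome signal when
#' random intercepts are present.
#'
#' @return A data frame with one row per predictor and columns `name`,
#'   `kind` (one of `"continuous"`, `"binary"`, `"ordinal"`,
#'   `"categorical"`, `"cluster-id"`) and `level` (the hierarchy level at
#'   which the variable is drawn: `"patient"`, `"doctor"` or `"hospital"`).
#' @examples
#' roster_default()
#' @export
roster_default <- function() {
  meta <- rbind(
    data.frame(
      name = c("Age", "Married", "FamilyHx", "SmokingHx", "Sex",
               "CancerStage", "LengthofStay", "WBC", "RBC", "BMI",
               "IL6", "CRP", "tumorsize", "co2", "pain", "wound",
               "mobility", "ntumors", "nmorphine", "lungcapacity"),
      kind = c("continuous", "binary", "binary", "categorical", "binary",
               "ordinal", "continuous", "continuous", "continuous",
               "continuous", "continuous", "continuous", "continuous",
               "continuous", "ordinal", "ordinal", "ordinal", "continuous",
               "continuous", "continuous"),
      level = "patient",
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = c("Experience", "School", "Lawsuits", "DID"),
      kind = c("continuous", "binary", "continuous", "cluster-id"),
      level = "doctor",
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = c("Medicaid", "HID"),
      kind = c("continuous", "cluster-id"),
      level = "hospital",
      stringsAsFactors = FALSE
    )
  )
  rownames(meta) <- NULL
  meta
}

#' Configuration of the three-level hierarchy
#'
#' @param n_hospitals Number of hospitals (default 35).
#' @param doctors_per_hospital Inclusive integer range from which each
#'   hospital's doctor count is drawn uniformly (default `c(8, 15)`).
#' @param patients_per_doctor Inclusive integer range from which each
#'   doctor's patient count is drawn uniformly (default `c(2, 40)`).
#' @param seed Integer seed; the same configuration and seed always yield a
#'   bit-identical dataset.
#' @param on_degenerate What to do if a generated outcome has a single
#'   class: `"resample"` redraws with a derived seed (up to 10 attempts,
#'   with a warning), `"error"` fails immediately.
#' @return A list of class `"hierarchy_config"`.
#' @export
hierarchy_config <- function(n_hospitals = 35,
                             doctors_per_hospital = c(8, 15),
                             patients_per_doctor = c(2, 40),
                             seed = 1L,
                             on_degenerate = c("resample", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  if (!is_count(n_hospitals) || n_hospitals < 1) {
    stop_config("n_hospitals must be a positive integer")
  }
  check_range <- function(r, what) {
    if (length(r) != 2L || !all(r == as.integer(r)) || r[1] < 1 || r[1] > r[2]) {
      stop_config(what, " must be an integer range c(lo, hi) with 1 <= lo <= hi")
    }
  }
  check_range(doctors_per_hospital, "doctors_per_hospital")
  check_range(patients_per_doctor, "patients_per_doctor")
  structure(
    list(n_hospitals = as.integer(n_hospitals),
         doctors_per_hospital = as.integer(doctors_per_hospital),
         patients_per_doctor = as.integer(patients_per_doctor),
         seed = as.integer(seed),
         on_degenerate = on_degenerate),
    class = "hierarchy_config"
  )
}

#' Fixed and random effects of the outcome model
#'
#' The outcome is drawn as
#' `remission ~ Bernoulli(plogis(intercept + X beta + u_doctor + u_hospital))`
#' with independent Gaussian random intercepts per doctor and per hospital.
#' Fixed-effect coefficients are on the logit scale and apply to the
#' variables as emitted (categorical and ordinal variables enter the linear
#' predictor through their integer codes).
#'
#' @param fixed_effects Named numeric vector of logit-scale coefficients;
#'   names must be predictors from the roster.
#' @param intercept Logit-scale intercept.
#' @param sd_doctor,sd_hospital Nonnegative standard deviations of the
#'   doctor- and hospital-level random intercepts.
#' @return A list of class `"effect_spec"`.
#' @seealso [default_effects()] for the parameterization used by the
#'   replication harness.
#' @export
effect_spec <- function(fixed_effects = numeric(0), intercept = 0,
                        sd_doctor = 0, sd_hospital = 0) {
  if (length(fixed_effects) &&
      (is.null(names(fixed_effects)) || any(!nzchar(names(fixed_effects))))) {
    stop_config("fixed_effects must be a named numeric vector")
  }
  if (sd_doctor < 0 || sd_hospital < 0) {
    stop_config("random-intercept standard deviations must be nonnegative")
  }
  structure(
    list(fixed_effects = fixed_effects, intercept = intercept,
         sd_doctor = sd_doctor, sd_hospital = sd_hospital),
    class = "effect_spec"
  )
}

#' Default effect specification for the replication harness
#'
#' Six predictors carry nonzero coefficients (CancerStage, Experience,
#' mobility, FamilyHx, LengthofStay, SmokingHx) and both cluster levels have
#' positive random-intercept standard deviations, with stronger clustering
#' at the doctor level. The intercept puts the marginal remission
#' prevalence near one third.
#'
#' @return An [effect_spec()].
#' @export
default_effects <- function() {
  effect_spec(
    fixed_effects = c(CancerStage = -0.55, Experience = 0.13,
                      mobility = -0.35, FamilyHx = -1.0,
                      LengthofStay = -0.18, SmokingHx = -0.5),
    intercept = 2.0,
    sd_doctor = 1.0,
    sd_hospital = 0.5
  )
}

# Draw the predictor columns for a realized hierarchy. `hid`/`did` are
# per-patient cluster labels; doctor- and hospital-level variables are drawn
# once per cluster and replicated over its patients.
draw_predictors <- function(hid, did, n_doctors, n_hospitals) {
  n <- length(hid)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ord9 <- function(n, mu) as.numeric(clip(round(stats::rnorm(n, mu, 2)), 1, 9))

  # doctor-level draws, indexed by did
  experience_d <- clip(round(stats::rnorm(n_doctors, 17, 4)), 7, 28)
  school_d <- stats::rbinom(n_doctors, 1, 0.5)
  lawsuits_d <- stats::rpois(n_doctors, 1.5)
  # hospital-level draws, indexed by hid
  medicaid_h <- round(stats::runif(n_hospitals, 0.1, 0.8), 3)

  data.frame(
    Age = round(clip(stats::rnorm(n, 51, 10), 18, 90), 1),
    Married = stats::rbinom(n, 1, 0.6),
    FamilyHx = stats::rbinom(n, 1, 0.2),
    SmokingHx = sample(1:3, n, replace = TRUE, prob = c(0.55, 0.25, 0.20)),
    Sex = stats::rbinom(n, 1, 0.5),
    CancerStage = sample(1:4, n, replace = TRUE,
                         prob = c(0.35, 0.30, 0.22, 0.13)),
    LengthofStay = 1 + stats::rpois(n, 4.5),
    WBC = round(stats::rnorm(n, 6, 1.5), 2),
    RBC = round(stats::rnorm(n, 4.9, 0.5), 2),
    BMI = round(clip(stats::rnorm(n, 27, 4), 15, 50), 1),
    IL6 = round(stats::rgamma(n, shape = 2, scale = 2), 2),
    CRP = round(stats::rgamma(n, shape = 2, scale = 3), 2),
    tumorsize = round(stats::rnorm(n, 70, 10), 1),
    co2 = round(stats::rnorm(n, 1.6, 0.1), 3),
    pain = ord9(n, 5),
    wound = ord9(n, 5.5),
    mobility = ord9(n, 6),
    ntumors = pmin(stats::rpois(n, 2), 9),
    nmorphine = stats::rpois(n, 3),
    lungcapacity = round(stats::rbeta(n, 4.5, 1.5), 3),
    Experience = as.numeric(experience_d[did]),
    School = school_d[did],
    Lawsuits = as.numeric(lawsuits_d[did]),
    DID = did,
    Medicaid = medicaid_h[hid],
    HID = hid
  )
}

#' Generate a three-level hierarchical dataset with a binary remission outcome
#'
#' Patients are nested in doctors, doctors in hospitals. Doctor counts per
#' hospital and patient counts per doctor are drawn uniformly from the
#' configured inclusive ranges; the binary `remission` outcome follows a
#' random-intercept logistic model (see [effect_spec()]). Categorical and
#' ordinal predictors are emitted as integer codes; the sidecar metadata
#' (attribute `"variable_meta"`) records each variable's kind.
#'
#' @param config A [hierarchy_config()].
#' @param effects An [effect_spec()]; every fixed-effect name must be a
#'   roster predictor.
#' @param roster Variable metadata, by default [roster_default()].
#' @return A data frame of class `"hdp_data"` with one row per patient:
#'   `ID`, the 26 roster predictors and `remission` (0/1, both classes
#'   present). Attributes: `variable_meta` (the roster), `outcome`
#'   (`"remission"`).
#' @examples
#' d <- generate_hierarchy(hierarchy_config(n_hospitals = 4,
#'                                          doctors_per_hospital = c(2, 3),
#'                                          patients_per_doctor = c(3, 6),
#'                                          seed = 42),
#'                         default_effects())
#' table(d$remission)
#' @export
generate_hierarchy <- function(config = hierarchy_config(),
                               effects = default_effects(),
                               roster = roster_default()) {
  stopifnot(inherits(config, "hierarchy_config"),
            inherits(effects, "effect_spec"))
  bad <- setdiff(names(effects$fixed_effects), roster$name)
  if (length(bad)) {
    stop_config("fixed-effect names not in the variable roster: ",
                paste(bad, collapse = ", "))
  }

  gen_once <- function(seed) {
    with_seed(seed, {
      n_doc_per_hosp <- sample(
        seq(config$doctors_per_hospital[1], config$doctors_per_hospital[2]),
        config$n_hospitals, replace = TRUE)
      n_doctors <- sum(n_doc_per_hosp)
      doctor_hid <- rep(seq_len(config$n_hospitals), times = n_doc_per_hosp)
      n_pat_per_doc <- sample(
        seq(config$patients_per_doctor[1], config$patients_per_doctor[2]),
        n_doctors, replace = TRUE)
      did <- rep(seq_len(n_doctors), times = n_pat_per_doc)
      hid <- doctor_hid[did]
      n <- length(did)

      x <- draw_predictors(hid, did, n_doctors, config$n_hospitals)
      u_doc <- stats::rnorm(n_doctors, 0, effects$sd_doctor)
      u_hosp <- stats::rnorm(config$n_hospitals, 0, effects$sd_hospital)
      lp <- rep(effects$intercept, n) + u_doc[did] + u_hosp[hid]
      for (v in names(effects$fixed_effects)) {
        lp <- lp + effects$fixed_effects[[v]] * x[[v]]
      }
      x$remission <- stats::rbinom(n, 1, stats::plogis(lp))
      x <- cbind(ID = seq_len(n), x)
      x
    })
  }

  seed <- config$seed
  for (attempt in 1:10) {
    x <- gen_once(seed)
    if (length(unique(x$remission)) == 2L) break
    if (config$on_degenerate == "error") {
      stop_config("generated outcome has a single class")
    }
    warning("degenerate single-class outcome; resampling with derived seed",
            call. = FALSE)
    seed <- derive_seeds(seed, 1L, stream = 99L)
    if (attempt == 10) stop_config("outcome degenerate after 10 resamples")
  }

  attr(x, "variable_meta") <- roster
  attr(x, "outcome") <- "remission"
  class(x) <- c("hdp_data", "data.frame")
  x
}

#' Write / read a dataset as CSV with a JSON metadata sidecar
#'
#' `write_dataset()` writes the rows as a plain CSV with a header and the
#' variable metadata (name, kind, level, outcome name) as
#' `<path>.meta.json`. `read_dataset()` reverses it; if the sidecar is
#' missing, kinds are inferred (`0/1` columns as binary, `DID`/`HID` as
#' cluster identifiers, other numeric columns as continuous).
#'
#' @param x A dataset (data frame; `hdp_data` attributes are preserved).
#' @param path CSV file path.
#' @return `read_dataset()` returns an `hdp_data` data frame.
#' @export
write_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- attr(x, "variable_meta")
  if (!is.null(meta)) {
    jsonlite::write_json(
      list(outcome = attr(x, "outcome") %||% "remission", variables = meta),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @param meta_path Sidecar path; defaults to `<path>.meta.json`.
#' @export
read_dataset <- function(path, meta_path = paste0(path, ".meta.json")) {
  x <- utils::read.csv(path)
  if (file.exists(meta_path)) {
    side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    meta <- as.data.frame(side$variables, stringsAsFactors = FALSE)
    outcome <- side$outcome
  } else {
    outcome <- if ("remission" %in% names(x)) "remission" else names(x)[ncol(x)]
    vars <- setdiff(names(x), c("ID", outcome))
    meta <- infer_meta(x, vars)
  }
  attr(x, "variable_meta") <- meta
  attr(x, "outcome") <- outcome
  class(x) <- c("hdp_data", "data.frame")
  x
}

# Fallback metadata inference for plain data frames.
infer_meta <- function(df, vars) {
  kind <- vapply(vars, function(v) {
    col <- df[[v]]
    if (v %in% c("DID", "HID")) "cluster-id"
    else if (is.factor(col) || is.character(col)) "categorical"
    else if (all(col %in% c(0, 1))) "binary"
    else "continuous"
  }, character(1))
  data.frame(name = vars, kind = kind, level = NA_character_,
             stringsAsFactors = FALSE)
}
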
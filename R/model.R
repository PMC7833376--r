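# The multiplicative exponential risk model:
#   Ln = 1 - exp(-Qn * prod_i g_i * D^Z)
# with D the tumour diameter in mm, g_i the multiplier of the record's level
# on each prognostic factor, Qn a population interpolation parameter and Z
# an exponent fixed at 1 for lymph-node involvement.

#' Risk model parameter set
#'
#' Bundles the fitted population parameter Qn, the per-level multipliers g
#' and the exponent Z together with the factor scheme they were fitted
#' under.  Levels not supplied default to g = 1; the reserved level
#' `"unknown"` always has an implicit g = 1 (missing information must not
#' change the prediction) and may not be given a multiplier.
#'
#' @param qn Positive population interpolation parameter.
#' @param g Named list: one named numeric vector of positive multipliers per
#'   scheme feature (possibly partial).  `NULL` sets every g to 1.
#' @param z Diameter exponent; 1 for lymph-node involvement.
#' @param scheme The [sln_scheme()] declaring the factors.
#' @return Object of class `"sln_params"` with elements `qn`, `g`, `z`,
#'   `scheme`.
#' @export
sln_params <- function(qn, g = NULL, z = 1, scheme = sln_scheme()) {
  stopifnot(inherits(scheme, "sln_scheme"))
  if (!is.numeric(qn) || length(qn) != 1L || !is.finite(qn) || qn <= 0)
    stop("qn must be a single positive number")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("z must be a single finite number")
  levs <- factor_levels(scheme)
  full <- lapply(levs, function(l) stats::setNames(rep(1, length(l)), l))
  if (!is.null(g)) {
    bad <- setdiff(names(g), scheme$features)
    if (length(bad))
      stop("g given for factor(s) not in the scheme: ",
           paste(bad, collapse = ", "))
    for (f in names(g)) {
      v <- g[[f]]
      extra <- setdiff(names(v), levs[[f]])
      if (length(extra))
        stop("g[[", f, "]] names unknown level(s): ",
             paste(extra, collapse = ", "),
             if ("unknown" %in% extra)
               ' ("unknown" levels always have g = 1)' else "")
      if (!all(is.finite(v)) || any(v <= 0))
        stop("g[[", f, "]] must be positive and finite")
      full[[f]][names(v)] <- as.numeric(v)
    }
  }
  structure(list(qn = qn, g = full, z = z, scheme = scheme),
            class = "sln_params")
}

# Exponent eta = Qn * prod(g) * D^Z for every record; the model probability
# is 1 - exp(-eta).
.sln_eta <- function(params, cohort) {
  lv <- map_to_levels(cohort, params$scheme)
  gtot <- rep(1, nrow(cohort))
  for (f in params$scheme$features) {
    l <- lv[[f]]
    gi <- unname(params$g[[f]][l])
    gi[l == "unknown"] <- 1
    if (anyNA(gi))
      stop("record level not covered by the fitted scheme for factor ", f)
    gtot <- gtot * gi
  }
  params$qn * gtot * cohort$diameter_mm^params$z
}

# Probabilities are never clipped: an exponent large enough that 1-exp(-eta)
# would round to 1.0 is an error -- unless the parameter set carries a
# clamped multiplier (a stratum whose observed rate was exactly 0 or 1, see
# fit_factor_parameter), in which case a saturated probability for that
# stratum's members is the faithful moment-matched value and is allowed.
.eta_to_prob <- function(eta, ids = NULL, allow_saturation = FALSE) {
  over <- eta >= .max_eta()
  if (any(over) && !allow_saturation)
    stop("exponent overflow: probability would saturate at 1 for ",
         if (is.null(ids)) paste(sum(over), "record(s)")
         else paste("patient(s)", paste(utils::head(ids[over], 3L),
                                        collapse = ", ")),
         "; check diameters and parameters")
  -expm1(-eta)
}

.has_clamped_g <- function(params) {
  g <- unlist(params$g)
  any(g >= 1e6 | g <= 1e-6)
}

#' Predict the node-positivity probability of one record
#'
#' Evaluates `1 - exp(-Qn * prod(g) * D^Z)` for a single patient record.
#' Levels mapped to `"unknown"` contribute a factor of 1.
#'
#' @param params An [sln_params()] object.
#' @param record One-row cohort data frame.
#' @return Probability in `[0, 1)`.
#' @export
predict_probability <- function(params, record) {
  stopifnot(inherits(params, "sln_params"))
  record <- validate_cohort(record)
  if (nrow(record) != 1L) stop("record must be a single row")
  .eta_to_prob(.sln_eta(params, record), record$patient_id,
               allow_saturation = .has_clamped_g(params))
}

#' Score every record of a cohort
#'
#' Element-wise application of [predict_probability()], order preserved.
#'
#' @param params An [sln_params()] object.
#' @param cohort A cohort data frame (may be empty).
#' @return Data frame with columns `patient_id` and `probability`.
#' @export
score_cohort <- function(params, cohort) {
  stopifnot(inherits(params, "sln_params"))
  if (nrow(cohort) == 0L)
    return(data.frame(patient_id = character(), probability = numeric()))
  cohort <- validate_cohort(cohort)
  p <- .eta_to_prob(.sln_eta(params, cohort), cohort$patient_id,
                    allow_saturation = .has_clamped_g(params))
  data.frame(patient_id = cohort$patient_id, probability = p)
}

# Plain-list representation used for JSON serialization (params and cohort
# configs share it).
.params_to_list <- function(params) {
  list(qn = params$qn, z = params$z,
       features = as.list(params$scheme$features),
       age_bins = list(breaks = params$scheme$age_bins$breaks,
                       labels = as.list(params$scheme$age_bins$labels)),
       g = lapply(params$g, as.list))
}

.params_from_list <- function(x) {
  bins <- age_bins(unlist(x$age_bins$breaks),
                   unlist(x$age_bins$labels))
  scheme <- sln_scheme(unlist(x$features) %||% character(), bins)
  g <- lapply(x$g, function(v) unlist(v))
  sln_params(qn = x$qn, g = g, z = x$z, scheme = scheme)
}

#' Serialize fitted parameters to JSON
#'
#' Writes `{qn, z, features, age_bins, g}` with full decimal precision;
#' `read_params(write_params(p))` reproduces the parameters exactly as
#' written.
#'
#' @param params An [sln_params()] object.
#' @param path Output/input file path.
#' @return `read_params`: an [sln_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sln_params"))
  jsonlite::write_json(.params_to_list(params), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  .params_from_list(jsonlite::read_json(path))
}
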
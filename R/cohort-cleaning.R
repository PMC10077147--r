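#' ICD-9 cohort selection rules
#'
#' Encodes the coded inclusion rules: a patient-only diagnosis set
#' (cardiogenic / unspecified shock), a shared diagnosis set (acute
#' myocardial infarction range, other acute ischemic heart disease, angina
#' pectoris) and the catheterisation/revascularisation procedure codes both
#' groups must carry under strict selection.  `mode = "relaxed"` is the
#' pre-imputation expansion: any diagnosis from the union qualifies and
#' procedures are ignored.
#'
#' @param patient_only_dx,shared_dx ICD-9 diagnosis code sets (character;
#'   ranges already expanded — see [expand_icd9_range()]).
#' @param required_procedures ICD-9 procedure codes.
#' @param mode `"strict"` or `"relaxed"`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(patient_only_dx = c("78551", "78550"),
                        shared_dx = c(expand_icd9_range("41000", "41092"),
                                      "41189", "4139"),
                        required_procedures = c("0066", "3604", "3606",
                                                "3607", "3609", "8855",
                                                "8856", "8857", "3722",
                                                "3723"),
                        mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  patient_only_dx <- vapply(patient_only_dx, normalize_icd9, "",
                            USE.NAMES = FALSE)
  shared_dx <- vapply(shared_dx, normalize_icd9, "", USE.NAMES = FALSE)
  required_procedures <- vapply(required_procedures, normalize_icd9, "",
                                USE.NAMES = FALSE)
  if (length(intersect(patient_only_dx, shared_dx)))
    stop("patient_only_dx and shared_dx must be disjoint")
  if (mode == "strict" && length(required_procedures) < 1)
    stop("strict mode requires at least one procedure code")
  structure(list(patient_only_dx = patient_only_dx, shared_dx = shared_dx,
                 required_procedures = required_procedures, mode = mode),
            class = "cohort_spec")
}

#' Normalise an ICD-9 code
#'
#' Strips dots and whitespace; errors if anything non-numeric remains
#' (synthetic/clinical numeric ICD-9 only; V/E codes are out of scope).
#' @param code character scalar.
#' @param context optional string included in error messages.
#' @return normalised character code.
#' @export
normalize_icd9 <- function(code, context = NULL) {
  x <- gsub("[. ]", "", as.character(code))
  if (!grepl("^[0-9]+$", x))
    stop("unparseable ICD-9 code '", code, "'",
         if (!is.null(context)) paste0(" (", context, ")") else "")
  x
}

#' Expand a numeric ICD-9 range to zero-padded 5-character codes
#'
#' Published inclusion tables print ranges such as 41000–41092; coded EHR
#' tables store each code as a zero-padded string.
#' @param from,to range endpoints (numeric or string).
#' @return character vector of codes.
#' @export
expand_icd9_range <- function(from, to) {
  from <- as.integer(normalize_icd9(from)); to <- as.integer(normalize_icd9(to))
  stopifnot(from <= to)
  sprintf("%05d", from:to)
}

#' Assign each subject to patient / control / excluded
#'
#' Strict mode: *patient* requires at least one patient-only diagnosis and
#' at least one required procedure; *control* requires at least one shared
#' diagnosis, at least one required procedure, and no patient-only
#' diagnosis; everyone else is *excluded*.  Relaxed mode (pre-imputation
#' expansion) includes any subject carrying any diagnosis from either set,
#' procedures ignored; the patient/control split is kept (patient iff any
#' patient-only code) since downstream stages still need a label.
#'
#' @param diagnoses data.frame with columns `subject_id`, `icd9_code`
#'   (rows of `type != "diagnosis"` are ignored if a `type` column exists).
#' @param procedures data.frame with the same layout (or the same combined
#'   table with `type == "procedure"`).
#' @param spec a [cohort_spec()].
#' @return data.frame `subject_id`, `group` (factor patient/control/excluded).
#' @export
select_cohort <- function(diagnoses, procedures, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pick <- function(d, want) {
    if (!is.null(d$type)) d <- d[d$type == want, , drop = FALSE]
    d
  }
  dx <- pick(diagnoses, "diagnosis")
  pr <- pick(procedures, "procedure")
  dx$icd9_code <- mapply(normalize_icd9, dx$icd9_code,
                         sprintf("diagnosis row %d", seq_len(nrow(dx))))
  if (nrow(pr))
    pr$icd9_code <- mapply(normalize_icd9, pr$icd9_code,
                           sprintf("procedure row %d", seq_len(nrow(pr))))
  subjects <- sort(unique(c(dx$subject_id, pr$subject_id)))
  has_code <- function(tab, codes)
    subjects %in% tab$subject_id[tab$icd9_code %in% codes]
  p_only <- has_code(dx, spec$patient_only_dx)
  shared <- has_code(dx, spec$shared_dx)
  proc <- if (nrow(pr)) has_code(pr, spec$required_procedures)
          else rep(FALSE, length(subjects))
  group <- rep("excluded", length(subjects))
  if (spec$mode == "strict") {
    group[p_only & proc] <- "patient"
    group[!p_only & shared & proc] <- "control"
  } else {
    group[p_only] <- "patient"
    group[!p_only & shared] <- "control"
  }
  data.frame(subject_id = subjects,
             group = factor(group, levels = c("patient", "control", "excluded")),
             stringsAsFactors = FALSE)
}

#' Definition of one aggregated clinical variable
#'
#' Real EHRs store the same quantity under several item codes; a cluster
#' names the target variable, its source codes with per-code native units,
#' and the ranges used by [repair_or_drop()]: `plausible_range` (soft; the
#' landing zone a decimal-shift repair must hit) and `hard_range` (values
#' outside are deleted).
#'
#' @param target aggregated variable name.
#' @param codes character vector of source item codes.
#' @param unit target unit (continuous only).
#' @param type `"continuous"` or `"categorical"`.
#' @param plausible_range,hard_range length-2 numeric `c(lo, hi)`;
#'   `plausible_range` must sit inside `hard_range`.
#' @return object of class `variable_cluster`.
#' @export
variable_cluster <- function(target, codes, unit = NA_character_,
                             type = c("continuous", "categorical"),
                             plausible_range = c(-Inf, Inf),
                             hard_range = c(-Inf, Inf)) {
  type <- match.arg(type)
  stopifnot(length(codes) >= 1,
            length(plausible_range) == 2, length(hard_range) == 2,
            plausible_range[1] < plausible_range[2],
            hard_range[1] < hard_range[2],
            hard_range[1] <= plausible_range[1],
            plausible_range[2] <= hard_range[2])
  structure(list(target = target, codes = codes, unit = unit, type = type,
                 plausible_range = plausible_range, hard_range = hard_range),
            class = "variable_cluster")
}

#' Default variable clusters matching the synthetic code map
#'
#' Hard/plausible ranges are shipped defaults for the model variables
#' (config-overridable); published cleaning rules give only the body
#' temperature example, so the rest are standard physiologic bounds.
#' @param variables list of [variable_spec()]s.
#' @param code_map a code map as from [default_code_map()].
#' @return named list of [variable_cluster()]s.
#' @export
default_clusters <- function(variables = default_variable_specs(),
                             code_map = default_code_map(variables)) {
  # plausible = clinical landing zone for a decimal-shift repair; hard =
  # deletion bounds for order-of-magnitude entry errors.  Hard bounds are
  # deliberately generous (±8 SD of the reference marginals) so genuine
  # distribution tails are never deleted — only gross slips like a
  # tenfold-shifted reading fall outside.
  ranges <- list(  # name -> list(plausible, hard)
    heart_rate = list(c(20, 250), c(-70, 300)),
    respiratory_rate = list(c(4, 60), c(-30, 99)),
    spo2 = list(c(50, 100), c(20, 140)),
    glucose = list(c(20, 1000), c(-900, 2000)),
    systolic_bp = list(c(40, 260), c(-100, 350)),
    age = list(c(15, 100), c(-40, 200)),
    o2_flow = list(c(0.5, 60), c(-30, 100)),
    temperature = list(c(30, 43), c(25, 45))
  )
  out <- lapply(names(variables), function(nm) {
    v <- variables[[nm]]
    r <- ranges[[nm]] %||% list(c(-Inf, Inf), c(-Inf, Inf))
    variable_cluster(nm, code_map[[nm]]$codes, unit = v$unit,
                     type = v$vtype,
                     plausible_range = r[[1]], hard_range = r[[2]])
  })
  stats::setNames(out, names(variables))
}

# unit-conversion registry ---------------------------------------------------

.unit_registry <- new.env(parent = emptyenv())

register_conversion <- function(from, to, fn) {
  assign(paste(from, to, sep = "->"), fn, envir = .unit_registry)
}
register_conversion("F", "C", function(x) (x - 32) * 5 / 9)
register_conversion("C", "F", function(x) x * 9 / 5 + 32)
register_conversion("in", "cm", function(x) x * 2.54)
register_conversion("cm", "in", function(x) x / 2.54)
register_conversion("lb", "kg", function(x) x * 0.45359237)
register_conversion("kg", "lb", function(x) x / 0.45359237)

#' Convert a value between registered clinical units
#'
#' Identity when the units are equal (or either is `NA`); otherwise applies
#' the registered exact arithmetic conversion (Fahrenheit/Celsius,
#' inch/cm, lb/kg).
#' @param value numeric vector.
#' @param from_unit,to_unit unit labels.
#' @return converted numeric vector.
#' @export
convert_unit <- function(value, from_unit, to_unit) {
  if (is.na(from_unit) || is.na(to_unit) || identical(from_unit, to_unit))
    return(value)
  key <- paste(from_unit, to_unit, sep = "->")
  if (!exists(key, envir = .unit_registry))
    stop("no registered conversion '", key, "'; known: ",
         paste(ls(.unit_registry), collapse = ", "))
  get(key, envir = .unit_registry)(value)
}

#' Decimal-shift repair or deletion of an implausible value
#'
#' A value outside the hard range whose tenth lands in the plausible range
#' is treated as a decimal-entry slip and divided by 10 (the classic
#' "375 °C" chart typo); a value outside the hard range that cannot be
#' repaired is deleted (`NA`); in-range values pass unchanged.  The single
#' deterministic factor-10 rule keeps manual outlier correction
#' reproducible.
#'
#' @param value numeric vector.
#' @param cluster a [variable_cluster()] supplying the ranges.
#' @return list `value` (numeric, `NA` where deleted) and `action`
#'   (character: `"kept"`, `"repaired"`, `"deleted"`, `NA` for input `NA`).
#' @export
repair_or_drop <- function(value, cluster) {
  stopifnot(inherits(cluster, "variable_cluster"))
  pr <- cluster$plausible_range; hr <- cluster$hard_range
  out <- value
  action <- rep(NA_character_, length(value))
  obs <- !is.na(value)
  in_hard <- obs & value >= hr[1] & value <= hr[2]
  repairable <- obs & !in_hard & (value / 10 >= pr[1]) & (value / 10 <= pr[2])
  deleted <- obs & !in_hard & !repairable
  action[in_hard] <- "kept"
  action[repairable] <- "repaired"
  action[deleted] <- "deleted"
  out[repairable] <- value[repairable] / 10
  out[deleted] <- NA
  list(value = out, action = action)
}

#' First-recorded aggregation of a long event table
#'
#' For every stay and every cluster, the value of the earliest-timestamped
#' event among the cluster's source codes, after per-event unit conversion
#' to the cluster's target unit.  Timestamp ties are broken
#' lexicographically by source item code (then by value, for full
#' determinism on degenerate fixtures).  No event for a cluster means a
#' missing cell.  Row order of the input is irrelevant.
#'
#' @param events data.frame: `subject_id`, `stay_id` (optional; falls back
#'   to `subject_id`), `item_code`, `charttime` (POSIXct or sortable
#'   string), `value`, `unit` (optional).
#' @param clusters list of [variable_cluster()]s; a source code present in
#'   two clusters is a configuration error.
#' @return a [feature_matrix()] with one row per stay (sorted by stay id).
#' @export
aggregate_first_recorded <- function(events, clusters) {
  stopifnot(is.data.frame(events), length(clusters) >= 1)
  all_codes <- unlist(lapply(clusters, `[[`, "codes"))
  if (anyDuplicated(all_codes))
    stop("source code(s) assigned to more than one cluster: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  if (is.null(events$stay_id)) events$stay_id <- events$subject_id
  if (is.null(events$unit)) events$unit <- NA_character_
  stays <- sort(unique(events$stay_id))
  sid <- events$subject_id[match(stays, events$stay_id)]

  cols <- list(); meta <- list()
  for (cl in clusters) {
    e <- events[events$item_code %in% cl$codes, , drop = FALSE]
    colv <- if (cl$type == "continuous") rep(NA_real_, length(stays))
            else rep(NA_character_, length(stays))
    if (nrow(e)) {
      val <- if (cl$type == "continuous") as.numeric(e$value)
             else as.character(e$value)
      if (cl$type == "continuous") {
        for (u in unique(e$unit)) {
          r <- which((is.na(e$unit) & is.na(u)) |
                     (!is.na(e$unit) & !is.na(u) & e$unit == u))
          val[r] <- convert_unit(val[r], u, cl$unit)
        }
      }
      ord <- order(e$stay_id, e$charttime, e$item_code, val)
      e <- e[ord, , drop = FALSE]; val <- val[ord]
      first <- !duplicated(e$stay_id)
      colv[match(e$stay_id[first], stays)] <- val[first]
    }
    cols[[cl$target]] <- colv
    meta[[cl$target]] <- data.frame(
      name = cl$target, type = cl$type, unit = cl$unit,
      levels = NA_character_, stringsAsFactors = FALSE)
  }
  feature_matrix(as.data.frame(cols, stringsAsFactors = FALSE),
                 do.call(rbind, meta), subject_id = sid)
}

#' Clean a raw event table into a feature matrix
#'
#' [aggregate_first_recorded()] followed by per-cell [repair_or_drop()] on
#' continuous variables; every repair and deletion is logged one line per
#' cell (subject, variable, old -> new).
#'
#' @inheritParams aggregate_first_recorded
#' @return list `fm` (cleaned [feature_matrix()]) and `log` (character).
#' @export
clean_events <- function(events, clusters) {
  fm <- aggregate_first_recorded(events, clusters)
  log <- character(0)
  for (cl in clusters) {
    if (cl$type != "continuous") next
    rd <- repair_or_drop(fm$data[[cl$target]], cl)
    chg <- which(!is.na(rd$action) & rd$action != "kept")
    for (i in chg)
      log <- c(log, sprintf("%s %s %s %g -> %s",
                            fm$subject_id[i], cl$target, rd$action[i],
                            fm$data[[cl$target]][i],
                            if (rd$action[i] == "deleted") "NA"
                            else format(rd$value[i])))
    fm$data[[cl$target]] <- rd$value
  }
  list(fm = fm, log = log)
}

#' Per-variable and overall missingness fractions
#'
#' @param fm a [feature_matrix()].
#' @return list `per_variable` (named fractions) and `overall`.
#' @export
missingness_profile <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$data) == 0 || ncol(fm$data) == 0)
    stop("cannot profile an empty matrix")
  mm <- missing_mask(fm)
  list(per_variable = colMeans(mm), overall = mean(mm))
}
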
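#' Quantile function of a Gaussian mixture
#'
#' Vectorised numerical inversion (bisection) of the mixture CDF; used by
#' the Gaussian-copula sampler so that correlated uniforms can be pushed
#' through arbitrary per-class mixtures.
#' @keywords internal
qmixnorm <- function(p, weights, means, sds) {
  lo <- min(means - 10 * sds); hi <- max(means + 10 * sds)
  pmix <- function(x) {
    out <- 0
    for (i in seq_along(weights))
      out <- out + weights[i] * stats::pnorm(x, means[i], sds[i])
    out
  }
  lo <- rep(lo, length(p)); hi <- rep(hi, length(p))
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    below <- pmix(mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

rmixnorm <- function(n, weights, means, sds) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sds[comp])
}

#' Generate the complete (pre-masking) synthetic feature matrix
#'
#' Draws `n_controls + n_patients` subjects.  Each continuous variable is a
#' per-class Gaussian mixture; categorical variables are drawn from
#' per-class level frequencies.  If `config$correlation` is given, the
#' continuous variables are coupled through a Gaussian copula on that
#' rank-correlation matrix (marginals are preserved exactly); by default
#' they are independent.  No missingness is introduced here — see
#' [apply_mcar()].
#'
#' @param config a [cohort_gen_config()].
#' @return list with elements `fm` (complete [feature_matrix()]), `labels`
#'   (integer 0/1 vector, 1 = cardiogenic shock), and `truth` (data.frame of
#'   subject id, label and every true value — the ground-truth record for
#'   parameter-recovery tests).
#' @export
generate_feature_matrix <- function(config) {
  stopifnot(inherits(config, "cohort_gen_config"))
  n <- config$n_controls + config$n_patients
  labels <- c(rep(0L, config$n_controls), rep(1L, config$n_patients))
  vars <- config$variables
  cont_names <- names(vars)[vapply(vars, function(v) v$vtype == "continuous", TRUE)]

  with_seed(child_seed(config$seed, "features"), {
    U <- NULL
    if (!is.null(config$correlation) && length(cont_names) > 1) {
      R <- config$correlation[cont_names, cont_names]
      ev <- eigen(R, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
      Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% t(L)
      U <- stats::pnorm(Z)
      colnames(U) <- cont_names
    }
    cols <- vector("list", length(vars))
    names(cols) <- names(vars)
    for (nm in names(vars)) {
      v <- vars[[nm]]
      col <- if (v$vtype == "continuous") numeric(n) else character(n)
      for (cls in 0:1) {
        idx <- which(labels == cls)
        p <- if (cls == 0) v$class0_params else v$class1_params
        if (v$vtype == "continuous") {
          col[idx] <- if (!is.null(U))
            qmixnorm(U[idx, nm], p$weights, p$means, p$sds)
          else rmixnorm(length(idx), p$weights, p$means, p$sds)
        } else {
          col[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
        }
      }
      cols[[nm]] <- if (v$vtype == "categorical")
        factor(col, levels = names(v$class0_params)) else col
    }
  })

  meta <- data.frame(
    name = names(vars),
    type = vapply(vars, `[[`, "", "vtype"),
    unit = vapply(vars, function(v) v$unit %||% NA_character_, ""),
    levels = vapply(vars, function(v)
      if (v$vtype == "categorical") paste(names(v$class0_params), collapse = "|")
      else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  sid <- sprintf("S%05d", seq_len(n))
  fm <- feature_matrix(as.data.frame(cols), meta, subject_id = sid)
  truth <- data.frame(subject_id = sid, label = labels, as.data.frame(cols),
                      stringsAsFactors = FALSE)
  list(fm = fm, labels = labels, truth = truth)
}

#' Apply missing-completely-at-random masking
#'
#' Masks each cell of each variable independently with its per-variable
#' rate; the mechanism never looks at values or class labels, so the mask is
#' statistically independent of both (the defining property of MCAR).
#' Observed cells are returned bit-identical to the input.
#'
#' @param fm a [feature_matrix()].
#' @param rates named numeric vector of per-variable missingness fractions
#'   in `[0, 1]`; variables not named are left fully observed.
#' @param seed integer seed for the masking stream.
#' @return the masked [feature_matrix()].
#' @export
apply_mcar <- function(fm, rates, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(names(rates)) || !all(names(rates) %in% fm$meta$name))
    stop("rates must be named by variables present in the matrix")
  if (any(rates < 0 | rates > 1)) stop("missing rates must be in [0, 1]")
  n <- nrow(fm$data)
  with_seed(child_seed(seed, "mcar"), {
    for (nm in names(rates)) {
      if (rates[[nm]] == 0) next
      mask <- stats::runif(n) < rates[[nm]]
      fm$data[[nm]][mask] <- NA
    }
  })
  fm
}

#' One-stop synthetic cohort draw
#'
#' [generate_feature_matrix()] followed by [apply_mcar()] at the rates
#' declared in the variable specs.
#' @param config a [cohort_gen_config()].
#' @return list `fm` (masked), `fm_complete`, `labels`, `truth`.
#' @export
generate_cohort <- function(config) {
  g <- generate_feature_matrix(config)
  rates <- vapply(config$variables, `[[`, 0, "missing_rate")
  list(fm = apply_mcar(g$fm, rates, seed = config$seed),
       fm_complete = g$fm, labels = g$labels, truth = g$truth)
}

#' Default source-code map for the synthetic event emitter
#'
#' Assigns each variable two synthetic chart item codes (real EHRs store the
#' same clinical quantity under several codes); temperature's second code
#' records in degrees Fahrenheit to exercise unit conversion.
#' @param variables list of [variable_spec()]s.
#' @return named list: per variable, `codes` and per-code `units`.
#' @export
default_code_map <- function(variables = default_variable_specs()) {
  out <- lapply(variables, function(v) {
    codes <- paste0(v$name, c("_chart", "_alt"))
    units <- rep(v$unit %||% NA_character_, 2)
    if (identical(v$name, "temperature")) units <- c("C", "F")
    list(codes = codes, units = units)
  })
  stats::setNames(out, names(variables))
}

#' ICD-9 code pools used by the synthetic diagnosis emitter
#' @keywords internal
synthetic_code_pools <- function() {
  list(patient_only = c("78551", "78550"),
       shared = c(sprintf("%05d", 41000:41092), "41189", "4139"),
       procedures = c("0066", "3604", "3606", "3607", "3609",
                      "8855", "8856", "8857", "3722", "3723"))
}

#' Generate a long-format coded event table plus diagnosis/procedure rows
#'
#' Emits the synthetic cohort as raw EHR-like tables: one timestamped event
#' row per recorded observation (each variable appears under one of several
#' source item codes, in that code's native unit), plus ICD-9 diagnosis and
#' procedure rows consistent with the subject's class.  Replaying
#' [clean_events()] on the output reconstructs [generate_feature_matrix()]'s
#' matrix cell for cell: the earliest event of each variable carries the
#' true value; later duplicate-code events are noisy distractors.
#'
#' @param config a [cohort_gen_config()].
#' @param code_map output of [default_code_map()] (≥ 1 code per variable).
#' @param frac_relaxed_only fraction of subjects emitted *without* procedure
#'   codes; they fail strict cohorting but enter the relaxed (imputation)
#'   cohort, exercising the post-imputation restriction step.
#' @return list: `events` (subject_id, stay_id, item_code, charttime,
#'   value, unit), `coded` (subject_id, icd9_code, type), `fm`, `labels`,
#'   `truth` as in [generate_feature_matrix()].
#' @export
generate_event_table <- function(config, code_map = default_code_map(config$variables),
                                 frac_relaxed_only = 0) {
  stopifnot(inherits(config, "cohort_gen_config"))
  if (length(code_map) == 0 ||
      any(vapply(code_map, function(m) length(m$codes) < 1, TRUE)))
    stop("code_map must assign at least one source code per variable")
  missing_map <- setdiff(names(config$variables), names(code_map))
  if (length(missing_map))
    stop("code_map lacks entries for: ", paste(missing_map, collapse = ", "))

  g <- generate_feature_matrix(config)
  n <- nrow(g$fm$data)
  sid <- g$fm$subject_id
  stay <- sprintf("T%05d", seq_len(n))
  base_time <- as.POSIXct("2008-03-01 00:00:00", tz = "UTC")

  ev <- list(); k <- 0L
  with_seed(child_seed(config$seed, "events"), {
    for (nm in names(config$variables)) {
      map <- code_map[[nm]]
      truthv <- g$fm$data[[nm]]
      is_cont <- config$variables[[nm]]$vtype == "continuous"
      prim <- sample.int(length(map$codes), n, replace = TRUE)
      t1 <- stats::runif(n, 0, 22 * 3600)
      # primary event: the true value, in the chosen code's native unit
      unit_var <- config$variables[[nm]]$unit %||% NA_character_
      val1 <- if (is_cont) as.numeric(truthv) else as.character(truthv)
      for (ci in seq_along(map$codes)) {
        rows <- which(prim == ci)
        if (!length(rows)) next
        vals <- val1[rows]
        if (is_cont && !is.na(map$units[ci]) && !identical(map$units[ci], unit_var))
          vals <- convert_unit(vals, from_unit = unit_var, to_unit = map$units[ci])
        k <- k + 1L
        ev[[k]] <- data.frame(
          subject_id = sid[rows], stay_id = stay[rows],
          item_code = map$codes[ci],
          charttime = base_time + t1[rows],
          value = as.character(vals),
          unit = map$units[ci], stringsAsFactors = FALSE)
      }
      # distractor: a later reading under a different code, ~50% of subjects
      if (length(map$codes) >= 2) {
        has2 <- which(stats::runif(n) < 0.5)
        if (length(has2)) {
          alt <- ((prim[has2]) %% length(map$codes)) + 1L
          t2 <- t1[has2] + stats::runif(length(has2), 60, 7200)
          vals <- if (is_cont)
            as.numeric(truthv)[has2] + stats::rnorm(length(has2), 0, 1)
          else as.character(truthv)[has2]
          for (ci in unique(alt)) {
            rows <- which(alt == ci)
            v2 <- vals[rows]
            if (is_cont && !is.na(map$units[ci]) && !identical(map$units[ci], unit_var))
              v2 <- convert_unit(v2, from_unit = unit_var, to_unit = map$units[ci])
            k <- k + 1L
            ev[[k]] <- data.frame(
              subject_id = sid[has2][rows], stay_id = stay[has2][rows],
              item_code = map$codes[ci],
              charttime = base_time + t2[rows],
              value = as.character(v2),
              unit = map$units[ci], stringsAsFactors = FALSE)
          }
        }
      }
    }

    pools <- synthetic_code_pools()
    no_proc <- rep(FALSE, n)
    if (frac_relaxed_only > 0)
      no_proc <- stats::runif(n) < frac_relaxed_only
    coded <- list(); j <- 0L
    for (i in seq_len(n)) {
      dx <- sample(pools$shared, 1)
      if (g$labels[i] == 1L) dx <- c("78551", dx)
      j <- j + 1L
      coded[[j]] <- data.frame(subject_id = sid[i], icd9_code = dx,
                               type = "diagnosis", stringsAsFactors = FALSE)
      if (!no_proc[i]) {
        j <- j + 1L
        coded[[j]] <- data.frame(subject_id = sid[i],
                                 icd9_code = sample(pools$procedures, 1),
                                 type = "procedure", stringsAsFactors = FALSE)
      }
    }
  })

  events <- do.call(rbind, ev)
  events <- events[order(events$stay_id, events$item_code, events$charttime), ]
  rownames(events) <- NULL
  coded <- do.call(rbind, coded)
  rownames(coded) <- NULL
  list(events = events, coded = coded,
       fm = g$fm, labels = g$labels, truth = g$truth)
}

#' Write synthetic event/coded tables as CSV
#' @param sim output of [generate_event_table()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- sim$events
  ev$charttime <- format(ev$charttime, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  data.table::fwrite(ev, file.path(dir, "events.csv"))
  data.table::fwrite(sim$coded, file.path(dir, "coded.csv"))
  invisible(dir)
}
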
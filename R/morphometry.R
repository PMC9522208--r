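#' The eight spiracle labels in anterior-to-posterior anatomical order
#'
#' Scarab beetles carry one mesothoracic (S), one metathoracic (T) and six
#' abdominal (A1-A6) spiracles per side.
#'
#' @return Character vector `c("S","T","A1",...,"A6")`.
#' @export
spiracle_labels <- function() c("S", "T", "A1", "A2", "A3", "A4", "A5", "A6")

#' Elliptical opening area from two orthogonal diameters
#'
#' The spiracular opening is modelled as an ellipse whose axes are the
#' diameters measured in the transverse and sagittal planes, so
#' `area = pi * (d_t/2) * (d_s/2)`. Diameters are in mm; the area is
#' returned in cm^2, the unit all downstream biophysics works in.
#'
#' `literal_semi_axes = TRUE` instead treats the measured diameters as the
#' semi-axes themselves (`area = pi * d_t * d_s`, 4x larger); this reading of
#' the measurement convention is exposed only for sensitivity checks — it
#' breaks the circular limit (a circle of diameter d would not get area
#' pi d^2/4) and is not the default.
#'
#' @param d_transverse opening diameter in the transverse plane, mm.
#' @param d_sagittal opening diameter in the sagittal plane, mm.
#' @param literal_semi_axes treat diameters as semi-axes (see above).
#' @return Opening area, cm^2. Vectorized.
#' @examples
#' elliptical_area(2, 2)  # circle of radius 1 mm: pi/100 cm^2
#' elliptical_area(4, 2)
#' @export
elliptical_area <- function(d_transverse, d_sagittal, literal_semi_axes = FALSE) {
  if (any(!is.finite(d_transverse)) || any(d_transverse <= 0))
    stop("invalid measurement: 'd_transverse' must be finite and > 0")
  if (any(!is.finite(d_sagittal)) || any(d_sagittal <= 0))
    stop("invalid measurement: 'd_sagittal' must be finite and > 0")
  scale <- if (literal_semi_axes) 1 else 0.25
  pi * scale * d_transverse * d_sagittal / 100  # mm^2 -> cm^2
}

# Validate a long-form measurement table; returns the table invisibly.
validate_measurements <- function(x, require_complete = FALSE) {
  req <- c("specimen_id", "species", "sex", "mass_g", "spiracle",
           "d_transverse_mm", "d_sagittal_mm", "depth_mm")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("measurement table is missing columns: ", paste(miss, collapse = ", "))
  bad_lab <- !x$spiracle %in% spiracle_labels()
  if (any(bad_lab))
    stop("unknown spiracle label(s): ",
         paste(unique(x$spiracle[bad_lab]), collapse = ", "))
  if (!all(x$sex %in% c("M", "F", "unknown")))
    stop("sex must be one of M, F, unknown")
  for (col in c("mass_g", "d_transverse_mm", "d_sagittal_mm", "depth_mm")) {
    v <- x[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("invalid measurement: '", col, "' must be finite and > 0")
  }
  key <- paste(x$specimen_id, x$spiracle)
  if (anyDuplicated(key))
    stop("duplicate (specimen, spiracle) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  mass_per <- tapply(x$mass_g, x$specimen_id, function(m) length(unique(m)))
  if (any(mass_per > 1))
    stop("inconsistent mass within specimen(s): ",
         paste(names(mass_per)[mass_per > 1], collapse = ", "))
  if (require_complete) {
    tab <- table(x$specimen_id)
    inc <- names(tab)[tab < 8L]
    if (length(inc)) {
      detail <- vapply(inc, function(id) {
        missing <- setdiff(spiracle_labels(), x$spiracle[x$specimen_id == id])
        paste0(id, " (missing ", paste(missing, collapse = ","), ")")
      }, character(1))
      stop("incomplete specimen(s): ", paste(detail, collapse = "; "))
    }
  }
  invisible(x)
}

#' Derived geometric metrics for each measured spiracle
#'
#' Appends to a long-form measurement table the quantities the scaling
#' analysis regresses on body mass: opening area (cm^2), depth (cm), the
#' diffusive index area/depth (cm, proportional to Fick's-law conductance)
#' and the advective index area^2/depth (cm^3, proportional to Poiseuille
#' conductance).
#'
#' @param x a measurement table (see [read_measurement_table()]).
#' @param literal_semi_axes passed to [elliptical_area()].
#' @return `x` with columns `area_cm2`, `depth_cm`, `diff_index_cm`,
#'   `adv_index_cm3` appended.
#' @export
spiracle_morphometrics <- function(x, literal_semi_axes = FALSE) {
  validate_measurements(x)
  x$area_cm2 <- elliptical_area(x$d_transverse_mm, x$d_sagittal_mm,
                                literal_semi_axes = literal_semi_axes)
  x$depth_cm <- x$depth_mm / 10
  x$diff_index_cm <- x$area_cm2 / x$depth_cm
  x$adv_index_cm3 <- x$area_cm2^2 / x$depth_cm
  x
}

#' Whole-animal summed diffusive and advective indices
#'
#' Sums the per-spiracle indices over all eight spiracles and doubles the
#' result, because measurements cover one of the two bilaterally symmetric
#' sides. Specimens missing spiracles are an error by default; with
#' `impute = TRUE` a missing spiracle's indices are imputed by the mean of
#' conspecific specimens for that label (an error if no conspecific
#' measured it).
#'
#' @param x a measurement table.
#' @param impute impute missing spiracles from conspecific means.
#' @param literal_semi_axes passed to [elliptical_area()].
#' @return One row per specimen: `specimen_id`, `species`, `sex`, `mass_g`,
#'   `total_diff_cm` (2 * sum area/depth) and `total_adv_cm3`
#'   (2 * sum area^2/depth).
#' @export
specimen_totals <- function(x, impute = FALSE, literal_semi_axes = FALSE) {
  m <- spiracle_morphometrics(x, literal_semi_axes = literal_semi_axes)
  if (impute) {
    m <- impute_missing_spiracles(m)
  } else {
    validate_measurements(m, require_complete = TRUE)
  }
  ids <- unique(m$specimen_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- m[m$specimen_id == id, ]
    data.frame(specimen_id = id,
               species = s$species[1], sex = s$sex[1], mass_g = s$mass_g[1],
               total_diff_cm = 2 * sum(s$diff_index_cm),
               total_adv_cm3 = 2 * sum(s$adv_index_cm3),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Fill in missing (specimen, label) rows with conspecific mean indices.
impute_missing_spiracles <- function(m) {
  ids <- unique(m$specimen_id)
  add <- list()
  for (id in ids) {
    s <- m[m$specimen_id == id, ]
    for (lab in setdiff(spiracle_labels(), s$spiracle)) {
      donors <- m[m$species == s$species[1] & m$spiracle == lab, ]
      if (nrow(donors) == 0L)
        stop("cannot impute spiracle ", lab, " for specimen ", id,
             ": no conspecific measurement")
      row <- s[1, ]
      row$spiracle <- lab
      for (col in c("d_transverse_mm", "d_sagittal_mm", "depth_mm",
                    "area_cm2", "depth_cm", "diff_index_cm", "adv_index_cm3"))
        row[[col]] <- mean(donors[[col]])
      add[[length(add) + 1L]] <- row
    }
  }
  if (length(add)) m <- rbind(m, do.call(rbind, add))
  m
}

#' Read / write a spiracle measurement table
#'
#' Long-form CSV dialect: one row per measured spiracle, columns
#' `specimen_id, species, sex, mass_g, spiracle, d_transverse_mm,
#' d_sagittal_mm, depth_mm`; UTF-8, '.' decimal separator, lines starting
#' with '#' are comments. Reading validates the table and reports the
#' offending row on failure; `read_measurement_table(write_measurement_table(x))`
#' is the identity.
#'
#' @param path file path.
#' @return `read_measurement_table`: a validated `data.frame` (possibly with
#'   zero rows).
#' @export
read_measurement_table <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(specimen_id = "character",
                                      species = "character",
                                      sex = "character",
                                      spiracle = "character"))
  if (nrow(x) == 0L) {
    for (col in c("mass_g", "d_transverse_mm", "d_sagittal_mm", "depth_mm"))
      x[[col]] <- as.numeric(x[[col]])
    return(validate_measurements(x))
  }
  err <- tryCatch({ validate_measurements(x); NULL }, error = function(e) e)
  if (!is.null(err)) {
    # re-run row by row to locate the first offending data row
    for (i in seq_len(nrow(x))) {
      ok <- tryCatch({ validate_measurements(x[seq_len(i), , drop = FALSE]); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop("parse error in ", path, " at data row ", i, ": ",
                    conditionMessage(err))
    }
    stop("parse error in ", path, ": ", conditionMessage(err))
  }
  x
}

#' @rdname read_measurement_table
#' @param x a validated measurement table.
#' @export
write_measurement_table <- function(x, path) {
  if (nrow(x) > 0L) validate_measurements(x)
  cols <- c("specimen_id", "species", "sex", "mass_g", "spiracle",
            "d_transverse_mm", "d_sagittal_mm", "depth_mm")
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
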
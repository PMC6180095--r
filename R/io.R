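#' Read a triaxial time-series CSV
#'
#' Expects a header `time_s,<c1>,<c2>,<c3>` — `ax,ay,az` for linear
#' acceleration, `alx,aly,alz` for angular acceleration, `wx,wy,wz` for
#' angular velocity — with a uniform time grid. The unit is declared by
#' the caller since the file format does not carry it.
#'
#' @param path CSV file path.
#' @param unit Unit tag for the three channels (see [uniform_signal()]).
#' @return A [triax_signal()].
#' @export
read_triax_csv <- function(path, unit) {
  df <- utils::read.csv(path)
  if (ncol(df) != 4L || names(df)[1L] != "time_s")
    stop("expected columns time_s,<x>,<y>,<z>", call. = FALSE)
  tt <- df$time_s
  dts <- diff(tt)
  if (length(dts) < 1L || any(abs(dts - dts[1L]) > 1e-9 * max(abs(dts))))
    stop("time grid is not uniform", call. = FALSE)
  triax_from_vectors(df[[2L]], df[[3L]], df[[4L]],
                     dt = dts[1L], t0 = tt[1L], unit = unit)
}

#' Write a triaxial time-series CSV
#'
#' @param v A [triax_signal()].
#' @param path Output path.
#' @param channels Column names for the three channels.
#' @export
write_triax_csv <- function(v, path, channels = c("ax", "ay", "az")) {
  stopifnot(inherits(v, "triax_signal"), length(channels) == 3L)
  df <- data.frame(signal_times(v$x), v$x$samples, v$y$samples, v$z$samples)
  names(df) <- c("time_s", channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a material loading-curve CSV (`strain,stress_pa`)
#'
#' @param path CSV file path.
#' @return A [material_curve()].
#' @export
read_material_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("strain", "stress_pa") %in% names(df)))
    stop("expected columns strain,stress_pa", call. = FALSE)
  material_curve(df$strain, df$stress_pa)
}

#' Read a per-element field CSV (`element_id,value`)
#'
#' @param path CSV file path.
#' @param kind `"strain"` or `"stress"`, see [element_field()].
#' @return An [element_field()].
#' @export
read_field_csv <- function(path, kind = "strain") {
  df <- utils::read.csv(path)
  if (!all(c("element_id", "value") %in% names(df)))
    stop("expected columns element_id,value", call. = FALSE)
  element_field(df$value, kind = kind)
}

#' Read a kinematics summary table CSV
#'
#' Header `age_years,direction,hic,hic15,hic36,peak_lin_g,
#' peak_ang_acc_rad_s2,peak_ang_vel_rad_s,mps,skull_stress_mpa`
#' (tissue columns optional).
#'
#' @param path CSV file path.
#' @return A [kinematics_table()].
#' @export
read_kinematics_csv <- function(path) {
  kinematics_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a kinematics summary table CSV
#'
#' @param table A [kinematics_table()].
#' @param path Output path.
#' @export
write_kinematics_csv <- function(table, path) {
  stopifnot(inherits(table, "kinematics_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
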
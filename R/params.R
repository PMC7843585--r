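#' Grouped-phytomer response coefficients
#'
#' Coefficients of the log + linear response of organ-size percent change to
#' the density regressor for a contiguous phytomer group (ranks 6-11 or
#' 13-18): Y = A * ln(x) + B * rank + C, with Y in percent.
#'
#' @param A Dimensionless coefficient of the logarithmic density term.
#' @param B Percent change per unit phytomer rank.
#' @param C Percent intercept.
#' @return An object of class `group_params`.
#' @export
group_params <- function(A, B, C) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  structure(list(A = A, B = B, C = C), class = "group_params")
}

#' Ear-phytomer response coefficients
#'
#' The ear-bearing phytomer follows a plain linear response
#' Y = D * x + E (Y in percent).
#'
#' @param D Percent change per unit of the density regressor.
#' @param E Percent intercept.
#' @return An object of class `ear_params`.
#' @export
ear_params <- function(D, E) {
  stopifnot(is.finite(D), is.finite(E))
  structure(list(D = D, E = E), class = "ear_params")
}

#' Full density-response parameterization
#'
#' Bundles, for each of the six organ dimensions, the lower-group (ranks
#' 6-11) coefficients, the ear-phytomer coefficients (rank 12), and the
#' upper-group (ranks 13-18) coefficients, together with the regressor
#' convention.
#'
#' @param organs Named list; one entry per organ code, each a list with
#'   elements `lower` (`group_params`), `ear` (`ear_params`) and `upper`
#'   (`group_params`).
#' @param ear_rank Ear-bearing phytomer rank, strictly between the two
#'   grouped rank ranges. Default 12.
#' @param regressor_mode `"increment"` (x = density - reference, the
#'   default) or `"absolute"` (x = density).
#' @param reference_density Reference plant density, plants per square
#'   meter. Default 4.5.
#' @return An object of class `response_params`.
#' @export
response_params <- function(organs, ear_rank = 12L,
                            regressor_mode = c("increment", "absolute"),
                            reference_density = REFERENCE_DENSITY) {
  regressor_mode <- match.arg(regressor_mode)
  ear_rank <- as.integer(ear_rank)
  missing_organs <- setdiff(organ_codes(), names(organs))
  if (length(missing_organs)) {
    abort_missing_entry(sprintf("response_params incomplete; missing organ(s): %s",
                                paste(missing_organs, collapse = ", ")))
  }
  for (code in organ_codes()) {
    entry <- organs[[code]]
    if (!all(c("lower", "ear", "upper") %in% names(entry))) {
      abort_missing_entry(sprintf("organ %s lacks lower/ear/upper groups", code))
    }
    stopifnot(inherits(entry$lower, "group_params"),
              inherits(entry$ear, "ear_params"),
              inherits(entry$upper, "group_params"))
  }
  if (!(ear_rank > 11L && ear_rank < 13L)) {
    abort_domain("ear_rank must lie strictly between the lower (6-11) and upper (13-18) groups")
  }
  structure(list(organs = organs[organ_codes()], ear_rank = ear_rank,
                 regressor_mode = regressor_mode,
                 reference_density = reference_density),
            class = "response_params")
}

#' Default density-response parameterization
#'
#' The fitted coefficients of the organ-size response of maize hybrid ZD958
#' to increased plant density: the grouped log + linear model for phytomers
#' 6-11 and 13-18 and the linear model for the ear phytomer (rank 12).
#' These values are constants of the package and are not re-derived.
#'
#' @return A [response_params] object covering all six organ dimensions.
#' @examples
#' p <- default_params()
#' p$organs$LL$lower$A  # 2.99
#' @export
default_params <- function() {
  g <- function(A, B, C) group_params(A, B, C)
  e <- function(D, E) ear_params(D, E)
  response_params(list(
    LL = list(lower = g( 2.99,  0.12,   0.32), ear = e( 0.11,  1.70), upper = g(-7.09, -2.36, 39.64)),
    LW = list(lower = g(-4.34,  0.80,   7.07), ear = e(-1.17, -1.78), upper = g(-8.71,  0.73, 13.93)),
    SL = list(lower = g( 0.73, -2.46,  21.63), ear = e(-0.86, -0.12), upper = g(-4.49,  0.61,  8.41)),
    SW = list(lower = g(-8.99, -0.24,   4.92), ear = e(-1.93,  2.83), upper = g(-9.41,  0.09,  1.55)),
    IL = list(lower = g( 4.94, -2.01,  18.61), ear = e( 0.54,  0.73), upper = g( 2.91, -2.06, 32.08)),
    ID = list(lower = g(-7.69, -0.53, -11.36), ear = e(-1.63, -9.53), upper = g(-9.66,  0.07, -8.52))
  ))
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf("Density-response parameters (%s regressor, reference %.1f plants/m2, ear rank %d)\n",
              x$regressor_mode, x$reference_density, x$ear_rank))
  for (code in names(x$organs)) {
    o <- x$organs[[code]]
    cat(sprintf("  %s  lower A=%7.2f B=%6.2f C=%7.2f | ear D=%6.2f E=%6.2f | upper A=%7.2f B=%6.2f C=%7.2f\n",
                code, o$lower$A, o$lower$B, o$lower$C, o$ear$D, o$ear$E,
                o$upper$A, o$upper$B, o$upper$C))
  }
  invisible(x)
}

# full-precision numeric formatting so config round-trips are bit exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a response parameterization to a plain-text config
#'
#' Flat `key = value` lines keyed by organ code and group
#' (e.g. `LL.lower.A = 2.99`). The representation round-trips bit exactly
#' through [read_params_config()].
#'
#' @param params A [response_params] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "response_params"))
  lines <- c(
    paste0("ear_rank = ", params$ear_rank),
    paste0("regressor_mode = ", params$regressor_mode),
    paste0("reference_density = ", fmt_num(params$reference_density))
  )
  for (code in names(params$organs)) {
    o <- params$organs[[code]]
    lines <- c(lines,
      sprintf("%s.lower.A = %s", code, fmt_num(o$lower$A)),
      sprintf("%s.lower.B = %s", code, fmt_num(o$lower$B)),
      sprintf("%s.lower.C = %s", code, fmt_num(o$lower$C)),
      sprintf("%s.ear.D = %s",   code, fmt_num(o$ear$D)),
      sprintf("%s.ear.E = %s",   code, fmt_num(o$ear$E)),
      sprintf("%s.upper.A = %s", code, fmt_num(o$upper$A)),
      sprintf("%s.upper.B = %s", code, fmt_num(o$upper$B)),
      sprintf("%s.upper.C = %s", code, fmt_num(o$upper$C)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a response parameterization from a plain-text config
#'
#' Unknown keys are errors (fail fast); missing coefficients raise a
#' missing-entry error via [response_params()].
#'
#' @param path Config file written by [write_params_config()].
#' @return A [response_params] object.
#' @export
read_params_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
  kv <- regmatches(raw, regexec("^\\s*([A-Za-z_.0-9]+)\\s*=\\s*(.*\\S)\\s*$", raw))
  if (any(lengths(kv) != 3)) {
    abort_domain(sprintf("malformed config line(s): %s",
                         paste(raw[lengths(kv) != 3], collapse = "; ")))
  }
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  known_scalar <- c("ear_rank", "regressor_mode", "reference_density")
  coef_keys <- as.vector(outer(organ_codes(),
    c("lower.A", "lower.B", "lower.C", "ear.D", "ear.E",
      "upper.A", "upper.B", "upper.C"), paste, sep = "."))
  unknown <- setdiff(keys, c(known_scalar, coef_keys))
  if (length(unknown)) {
    abort_domain(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  lookup <- function(k) {
    i <- which(keys == k)
    if (!length(i)) abort_missing_entry(sprintf("config missing key: %s", k))
    vals[[i[[1]]]]
  }
  organs <- lapply(stats::setNames(organ_codes(), organ_codes()), function(code) {
    num <- function(k) as.numeric(lookup(paste(code, k, sep = ".")))
    list(lower = group_params(num("lower.A"), num("lower.B"), num("lower.C")),
         ear   = ear_params(num("ear.D"), num("ear.E")),
         upper = group_params(num("upper.A"), num("upper.B"), num("upper.C")))
  })
  response_params(organs,
                  ear_rank = as.integer(lookup("ear_rank")),
                  regressor_mode = lookup("regressor_mode"),
                  reference_density = as.numeric(lookup("reference_density")))
}
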
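# JSON serialization of band schemes: open limits (0 below, Inf above) are
# written as null; frequencies are decimal numbers at full precision.

#' Write a band scheme to JSON
#'
#' Serializes as `{f_ref, R, n_min, n_max, subdivide_alpha, bands: [{label,
#' n, center, lower, upper}]}` with open limits as `null`. The round trip
#' through [read_scheme_json()] is lossless at full floating precision.
#'
#' @param scheme A [band_scheme()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme_json <- function(scheme, path) {
  validate_band_scheme(scheme)
  b <- scheme$bands
  bands <- lapply(seq_len(nrow(b)), function(i) {
    list(label = b$label[i],
         n = if (is.na(b$n[i])) NULL else b$n[i],
         center = b$center[i],
         lower = if (b$lower[i] <= 0) NULL else b$lower[i],
         upper = if (is.infinite(b$upper[i])) NULL else b$upper[i])
  })
  obj <- list(
    f_ref = if (is.na(scheme$f_ref)) NULL else scheme$f_ref,
    R = if (is.na(scheme$R)) NULL else scheme$R,
    n_min = if (is.na(scheme$n_min)) NULL else scheme$n_min,
    n_max = if (is.na(scheme$n_max)) NULL else scheme$n_max,
    subdivide_alpha = scheme$subdivide_alpha,
    bands = bands
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a band scheme from JSON
#'
#' Inverse of [write_scheme_json()]: `null` limits become the open sentinels
#' (0 below, `Inf` above) and the reconstructed scheme is validated, so
#' hand-edited files with gaps or overlaps are rejected.
#'
#' @param path JSON file path.
#' @return A [band_scheme()].
#' @export
read_scheme_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$bands) || length(obj$bands) < 2L) {
    stop(sprintf("%s: not a scheme JSON (needs a `bands` array)", path),
         call. = FALSE)
  }
  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  bands <- do.call(rbind, lapply(obj$bands, function(bd) {
    if (is.null(bd$label) || is.null(bd$center)) {
      stop(sprintf("%s: each band needs `label` and `center`", path),
           call. = FALSE)
    }
    data.frame(label = as.character(bd$label),
               n = if (is.null(bd$n)) NA_integer_ else as.integer(bd$n),
               center = as.numeric(bd$center),
               lower = num_or(bd$lower, 0),
               upper = num_or(bd$upper, Inf),
               stringsAsFactors = FALSE)
  }))
  scheme <- structure(
    list(f_ref = num_or(obj$f_ref, NA_real_),
         R = num_or(obj$R, NA_real_),
         n_min = if (is.null(obj$n_min)) NA_integer_ else as.integer(obj$n_min),
         n_max = if (is.null(obj$n_max)) NA_integer_ else as.integer(obj$n_max),
         subdivide_alpha = isTRUE(obj$subdivide_alpha),
         bands = bands),
    class = "band_scheme"
  )
  validate_band_scheme(scheme)
}
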
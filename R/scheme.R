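#' Band-center frequency of the exponential scheme
#'
#' Centers follow the exponential law \eqn{f_n = f_{ref} \cdot R^n}: one
#' multiplicative step of the scaling ratio `R` per integer band index `n`,
#' with the reference band at `n = 0`. Under the defaults (`f_ref = 10.5`,
#' `R = 1.7275`) successive indices land on the delta, theta, alpha, beta and
#' gamma centers of the geometric scheme.
#'
#' @param f_ref Reference (anchor) frequency in Hz; must be positive.
#' @param R Dimensionless band-to-band scaling ratio; must be positive.
#' @param n Band index; integer for canonical bands, but any real value is
#'   accepted (the law is continuous in `n`). May be a vector.
#' @return Center frequency in Hz, same length as `n`.
#' @seealso [index_of()] for the inverse mapping, [band_scheme()].
#' @examples
#' center_frequency(10.5, 1.7275, -2:3)
#' @export
center_frequency <- function(f_ref, R, n) {
  check_positive_scalar(f_ref, "f_ref")
  check_positive_scalar(R, "R")
  stopifnot(is.numeric(n), length(n) >= 1L, all(is.finite(n)))
  f_ref * R^n
}

#' Continuous band index of a frequency
#'
#' Inverse of [center_frequency()]: `log(f / f_ref) / log(R)`. Maps any
#' positive frequency onto the continuous index axis of a scheme, so that
#' integer values fall on band centers and half-integers on boundaries
#' (geometric means of adjacent centers).
#'
#' @param f Frequency in Hz; positive, may be a vector.
#' @inheritParams center_frequency
#' @return Real-valued index, same length as `f`.
#' @examples
#' index_of(7.83, 10.5, 1.7275)
#' @export
index_of <- function(f, f_ref, R) {
  check_positive_vector(f, "f")
  check_positive_scalar(f_ref, "f_ref")
  check_positive_scalar(R, "R")
  if (R <= 1) stop("`R` must exceed 1 for the index to be well defined", call. = FALSE)
  log(f / f_ref) / log(R)
}

#' Geometric-mean boundary between two band centers
#'
#' The separation frequency between adjacent bands is the geometric mean
#' \eqn{\sqrt{f_a \cdot f_b}} of their centers, i.e. the midpoint on a
#' logarithmic frequency axis. This keeps the tessellation equally spaced in
#' log-frequency regardless of the scaling ratio.
#'
#' @param f_lower_center,f_upper_center Centers of the lower and upper band
#'   in Hz; positive, `f_lower_center <= f_upper_center` elementwise.
#'   Vectorized.
#' @return Boundary frequency in Hz.
#' @examples
#' geometric_boundary(6.07, 10.50)
#' @export
geometric_boundary <- function(f_lower_center, f_upper_center) {
  check_positive_vector(f_lower_center, "f_lower_center")
  check_positive_vector(f_upper_center, "f_upper_center")
  if (any(f_lower_center > f_upper_center)) {
    stop("`f_lower_center` must not exceed `f_upper_center`", call. = FALSE)
  }
  sqrt(f_lower_center * f_upper_center)
}

#' Band centers of the default scheme as conventionally tabulated
#'
#' Two-decimal center frequencies quoted for the default scheme
#' (`f_ref = 10.5`, `R = 1.7275`, `n = -2..3`). Three entries (6.07, 31.35,
#' 54.21) differ by one or more units in the last digit from exact rounding
#' of the full-precision centers (6.08, 31.33, 54.13); they are kept verbatim
#' because the familiar two-decimal boundary values (4.62, 7.98, 13.81,
#' 23.85, 41.22) are reproducible only from this tabulation. Use
#' `tbb_scheme(rounding = "tabulated")` to build a scheme on these centers.
#'
#' @format Named numeric vector of length 6 (names are the band indices).
#' @export
tbb_tabulated_centers <- c(
  `-2` = 3.52, `-1` = 6.07, `0` = 10.50, `1` = 18.14, `2` = 31.35, `3` = 54.21
)

default_band_labels <- function(n) {
  vapply(n, function(k) {
    if (k < -2) paste0("infra", -2L - k)
    else if (k == -2) "delta"
    else if (k == -1) "theta"
    else if (k == 0) "alpha"
    else if (k == 1) "beta"
    else paste0("gamma", k - 1L)
  }, character(1))
}

#' Construct a geometric band scheme
#'
#' Builds the full band tessellation: centers from the exponential law for
#' `n` in `n_min:n_max`, interior boundaries as geometric means of adjacent
#' full-precision centers, the lowest band open below (lower limit 0) and the
#' highest open above (upper limit `Inf`). Bands are lower-closed/upper-open
#' `[lower, upper)`, so a frequency equal to a shared boundary belongs to the
#' upper band. When `subdivide_alpha` is set, the `n = 0` band is split into
#' two sub-bands meeting exactly at `f_ref` (the split point doubles as the
#' band center).
#'
#' @inheritParams center_frequency
#' @param n_min,n_max Integer index range, `n_min < n_max`.
#' @param subdivide_alpha Split the `n = 0` band at `f_ref` into lower/upper
#'   sub-bands (labels get suffixes `1`/`2`). Ignored when 0 is outside the
#'   index range.
#' @param labels Optional character vector of band names, one per index
#'   before subdivision; defaults to delta, theta, alpha, beta, gamma1, ...
#' @param centers Optional numeric override of the centers (strictly
#'   increasing, one per index), e.g. a rounded tabulation; boundaries are
#'   then derived from these values instead of the exponential law.
#' @return An object of class `band_scheme`: a list with the construction
#'   parameters and a `bands` data frame (`label`, `n`, `center`, `lower`,
#'   `upper`).
#' @examples
#' band_scheme()
#' band_scheme(10.5, 2, -1, 1, subdivide_alpha = FALSE)
#' @export
band_scheme <- function(f_ref = 10.5, R = 1.7275, n_min = -2L, n_max = 3L,
                        subdivide_alpha = TRUE, labels = NULL, centers = NULL) {
  check_positive_scalar(f_ref, "f_ref")
  check_positive_scalar(R, "R")
  if (R <= 1) stop("`R` must exceed 1", call. = FALSE)
  stopifnot(length(n_min) == 1L, length(n_max) == 1L,
            n_min == round(n_min), n_max == round(n_max))
  if (n_min >= n_max) stop("`n_min` must be smaller than `n_max`", call. = FALSE)
  n <- as.integer(n_min):as.integer(n_max)

  if (is.null(centers)) {
    centers <- center_frequency(f_ref, R, n)
  } else {
    check_positive_vector(centers, "centers")
    if (length(centers) != length(n)) {
      stop("`centers` must supply one value per index n_min:n_max", call. = FALSE)
    }
    if (any(diff(centers) <= 0)) {
      stop("`centers` must be strictly increasing", call. = FALSE)
    }
  }

  if (is.null(labels)) {
    labels <- default_band_labels(n)
  } else if (length(labels) != length(n)) {
    stop("`labels` must supply one name per index n_min:n_max", call. = FALSE)
  }

  k <- length(n)
  bounds <- geometric_boundary(centers[-k], centers[-1])
  lower <- c(0, bounds)
  upper <- c(bounds, Inf)
  bands <- data.frame(
    label = labels, n = n, center = centers, lower = lower, upper = upper,
    stringsAsFactors = FALSE
  )

  if (isTRUE(subdivide_alpha) && 0L %in% n) {
    i <- match(0L, bands$n)
    split <- f_ref
    if (!(split > bands$lower[i] && split < bands$upper[i])) {
      stop("alpha split point f_ref does not fall inside the n = 0 band",
           call. = FALSE)
    }
    sub <- bands[c(i, i), ]
    sub$label <- paste0(bands$label[i], c("1", "2"))
    sub$upper[1] <- split
    sub$lower[2] <- split
    bands <- rbind(bands[seq_len(i - 1L), ], sub,
                   bands[seq_len(nrow(bands)) > i, ])
    rownames(bands) <- NULL
  }

  scheme <- structure(
    list(f_ref = f_ref, R = R, n_min = as.integer(n_min),
         n_max = as.integer(n_max), subdivide_alpha = isTRUE(subdivide_alpha),
         bands = bands),
    class = "band_scheme"
  )
  validate_band_scheme(scheme)
}

#' The default geometric scheme at either precision
#'
#' Convenience constructor for the default six-index scheme with the alpha
#' subdivision. `rounding = "full"` (default) computes everything at full
#' floating precision; `rounding = "tabulated"` builds the scheme on the
#' conventional two-decimal centers ([tbb_tabulated_centers]) so that the
#' familiar printed boundaries (4.62, 7.98, 13.81, 23.85, 41.22 Hz) are
#' reproduced to two decimals.
#'
#' @param rounding `"full"` or `"tabulated"`.
#' @return A `band_scheme`.
#' @examples
#' tbb_scheme()
#' tbb_scheme("tabulated")
#' @export
tbb_scheme <- function(rounding = c("full", "tabulated")) {
  rounding <- match.arg(rounding)
  centers <- if (rounding == "tabulated") unname(tbb_tabulated_centers) else NULL
  band_scheme(centers = centers)
}

#' Traditional EEG band definitions
#'
#' The conventional segmentation used as the comparison scheme: delta 1-4,
#' theta 4-8, alpha1 8-10, alpha2 10-13, beta 13-30, gamma 30-100 Hz. Not
#' generated by a geometric rule (`f_ref` and `R` are `NA`), but a valid
#' `band_scheme` for classification and band-power purposes.
#'
#' @return A `band_scheme`.
#' @export
traditional_scheme <- function() {
  bands <- data.frame(
    label = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    n = NA_integer_,
    center = c(2.5, 6, 9, 11.5, 21.5, 65),
    lower = c(1, 4, 8, 10, 13, 30),
    upper = c(4, 8, 10, 13, 30, 100),
    stringsAsFactors = FALSE
  )
  scheme <- structure(
    list(f_ref = NA_real_, R = NA_real_, n_min = NA_integer_,
         n_max = NA_integer_, subdivide_alpha = TRUE, bands = bands),
    class = "band_scheme"
  )
  validate_band_scheme(scheme)
}

#' Validate a band scheme's invariants
#'
#' Checks that bands are ordered, strictly increasing, tessellating (each
#' interior upper limit equals the next lower limit exactly) and that every
#' center lies within its band (boundary-inclusive for subdivided bands).
#'
#' @param scheme A `band_scheme`.
#' @return The scheme, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_band_scheme <- function(scheme) {
  if (!inherits(scheme, "band_scheme")) stop("not a band_scheme", call. = FALSE)
  b <- scheme$bands
  need <- c("label", "n", "center", "lower", "upper")
  if (!all(need %in% names(b))) stop("bands table is missing columns", call. = FALSE)
  if (nrow(b) < 2L) stop("a scheme needs at least two bands", call. = FALSE)
  if (any(b$lower >= b$upper)) stop("every band needs lower < upper", call. = FALSE)
  if (any(b$center < b$lower | b$center > b$upper)) {
    stop("band centers must lie within their bands", call. = FALSE)
  }
  if (any(abs(b$upper[-nrow(b)] - b$lower[-1]) > 0)) {
    stop("bands must tessellate: interior upper limits must equal the next lower limit",
         call. = FALSE)
  }
  if (any(diff(b$center) < 0)) stop("band centers must be non-decreasing", call. = FALSE)
  if (anyDuplicated(b$label)) stop("band labels must be unique", call. = FALSE)
  scheme
}

#' Re-anchor a geometric scheme at a new reference frequency
#'
#' Rebuilds the scheme with the same ratio, index range, subdivision and
#' labels but a new anchor, e.g. an individual alpha frequency from
#' [estimate_iaf()]. Only the reference moves; the ratio `R` is kept fixed
#' (use [estimate_geometric_ratio()] to refit both from observed peaks).
#'
#' @param scheme A geometric `band_scheme` (one built by [band_scheme()]).
#' @param f_ref New reference frequency in Hz, or an `anchor_estimate`.
#' @return A new `band_scheme`.
#' @export
reanchor <- function(scheme, f_ref) {
  validate_band_scheme(scheme)
  if (is.na(scheme$f_ref)) {
    stop("scheme was not built from a geometric rule; cannot re-anchor", call. = FALSE)
  }
  if (inherits(f_ref, "anchor_estimate")) f_ref <- f_ref$value
  band_scheme(f_ref = f_ref, R = scheme$R, n_min = scheme$n_min,
              n_max = scheme$n_max, subdivide_alpha = scheme$subdivide_alpha)
}

#' Classical Titius-Bode band centers
#'
#' The classical (pre-refinement) progression uses additive multipliers
#' `0.4 + 0.3 * 2^m` rather than a constant ratio. Anchoring the alpha band
#' at multiplier 1.0 (`m = 1`) gives theta the `m = 0` multiplier 0.7, delta
#' the limiting `m -> -Inf` multiplier 0.4, and beta the `m = 2` multiplier
#' 1.6. With a 10.5 Hz anchor the theta center is 7.35 Hz, about 6% below the
#' 7.83 Hz fundamental Schumann mode.
#'
#' @param f_ref Anchor frequency in Hz (alpha center).
#' @return Data frame with `label`, `m`, `multiplier` and `center` (Hz).
#' @examples
#' classical_tb_centers(10.5)
#' @export
classical_tb_centers <- function(f_ref) {
  check_positive_scalar(f_ref, "f_ref")
  m <- c(-Inf, 0, 1, 2)
  mult <- 0.4 + 0.3 * 2^m
  data.frame(
    label = c("delta", "theta", "alpha", "beta"),
    m = m, multiplier = mult, center = mult * f_ref,
    stringsAsFactors = FALSE
  )
}

# centers plus closed (finite, interior) boundaries of a scheme, as the
# feature set used by alignment metrics
scheme_features <- function(scheme) {
  b <- scheme$bands
  centers <- data.frame(kind = "center", label = b$label, freq = b$center,
                        stringsAsFactors = FALSE)
  centers <- centers[!duplicated(centers$freq), ]
  ib <- b$lower[-1]
  keep <- is.finite(ib) & ib > 0
  boundaries <- data.frame(
    kind = "boundary",
    label = paste0(b$label[-nrow(b)], "/", b$label[-1])[keep],
    freq = ib[keep], stringsAsFactors = FALSE
  )
  feats <- rbind(centers, boundaries)
  feats <- feats[order(feats$freq, feats$kind), ]
  rownames(feats) <- NULL
  feats
}

format_band_range <- function(lower, upper, digits = 2) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  ifelse(lower <= 0, paste0("f < ", fmt(upper)),
         ifelse(is.infinite(upper), paste0("f > ", fmt(lower)),
                paste0(fmt(lower), "-", fmt(upper))))
}

#' @export
print.band_scheme <- function(x, digits = 2, ...) {
  if (is.na(x$f_ref)) {
    cat("Band scheme (explicit ranges)\n")
  } else {
    cat(sprintf("Geometric band scheme: f_ref = %g Hz, R = %g, n = %d..%d%s\n",
                x$f_ref, x$R, x$n_min, x$n_max,
                if (x$subdivide_alpha) ", alpha subdivided" else ""))
  }
  b <- x$bands
  out <- data.frame(
    label = b$label, n = b$n,
    center = round(b$center, digits),
    range = format_band_range(b$lower, b$upper, digits),
    stringsAsFactors = FALSE
  )
  print(out, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.band_scheme <- function(x, ...) x$bands

# shared argument checks ----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_positive_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
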
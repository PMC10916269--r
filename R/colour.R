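#' sRGB to CIELAB conversion
#'
#' Standard conversion chain sRGB -> linear RGB -> XYZ -> CIELAB via
#' [grDevices::convertColor()], with a D65 reference white by default.
#'
#' @param rgb numeric vector of length 3 or a 3-column matrix of sRGB
#'   channels in `[0, 1]`.
#' @param white reference white passed to the Lab conversion (default
#'   `"D65"`).
#' @return data.frame with columns `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(rgb, white = "D65") {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(rgb) != 3) stop("rgb must have three channels")
  if (any(rgb < 0 | rgb > 1)) stop("sRGB channels must lie in [0, 1]")
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab",
                                 to.ref.white = white)
  data.frame(L = lab[, 1], a = lab[, 2], b = lab[, 3])
}

#' Colourimetric indices for tuber flesh phenotyping
#'
#' Computes from CIELAB coordinates the indices commonly used to phenotype
#' flesh colour:
#' \describe{
#'   \item{WI}{whiteness index `100 - sqrt((100 - L)^2 + a^2 + b^2)`;
#'     equals 100 only for perfect white `(100, 0, 0)`.}
#'   \item{YI}{yellowness index `142.86 * b / L`.}
#'   \item{CIRG}{colour index of red grapes `(180 - h) / (L + C)` with the
#'     hue angle `h` in unsigned degrees and chroma `C = sqrt(a^2 + b^2)`.}
#'   \item{HI}{hue angle `atan2(b, a)` in degrees; the signed convention
#'     `(-180, 180]` is the default (purple-fleshed samples then take
#'     negative values), the unsigned convention reports `[0, 360)`.}
#'   \item{BI}{browning index `100 * (x - 0.31) / 0.172` with
#'     `x = (a + 1.75 L) / (5.645 L + a - 3.012 b)`.}
#' }
#' `L = 0` leaves YI and BI undefined (`NA` with a warning).
#'
#' @param L,a,b numeric vectors of CIELAB coordinates (`L` in `[0, 100]`).
#' @param hue `"signed"` (default) or `"unsigned"` convention for HI.
#' @return data.frame with columns `WI`, `YI`, `CIRG`, `HI`, `BI`.
#' @export
colour_indices <- function(L, a, b, hue = c("signed", "unsigned")) {
  hue <- match.arg(hue)
  if (any(L < 0 | L > 100)) stop("L must lie in [0, 100]")
  chroma <- sqrt(a^2 + b^2)
  h_signed <- atan2(b, a) * 180 / pi           # (-180, 180]
  h_unsigned <- h_signed %% 360                # [0, 360)
  wi <- 100 - sqrt((100 - L)^2 + a^2 + b^2)
  zero <- L == 0
  if (any(zero))
    warning("YI and BI undefined at L = 0; returning NA")
  yi <- ifelse(zero, NA_real_, 142.86 * b / L)
  x <- (a + 1.75 * L) / (5.645 * L + a - 3.012 * b)
  bi <- ifelse(zero, NA_real_, 100 * (x - 0.31) / 0.172)
  cirg <- (180 - h_unsigned) / (L + chroma)
  data.frame(WI = wi, YI = yi, CIRG = cirg,
             HI = if (hue == "signed") h_signed else h_unsigned, BI = bi)
}

#' Phenotype-table quality control and descriptive statistics
#'
#' Validates a long-format phenotype table (unique
#' `(sample, trait, location, replicate)` keys, finite numeric values) and
#' returns per-trait descriptive statistics, overall and per location. A
#' single observation leaves the SD undefined (`NA`, the `n - 1`
#' denominator convention).
#'
#' @param phenotypes data.frame with columns `sample`, `trait`, `location`,
#'   `replicate`, `value`.
#' @return list with `overall` and `by_location` data.frames (`trait`,
#'   [`location`,] `n`, `mean`, `sd`, `min`, `max`).
#' @export
phenotype_qc <- function(phenotypes) {
  req <- c("sample", "trait", "location", "replicate", "value")
  stopifnot(all(req %in% names(phenotypes)))
  if (!is.numeric(phenotypes$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(phenotypes$value))))[1]
    stop("non-numeric phenotype value in row ", bad)
  }
  if (any(!is.finite(phenotypes$value)))
    stop("non-finite phenotype value in row ",
         which(!is.finite(phenotypes$value))[1])
  key <- do.call(paste, phenotypes[c("sample", "trait", "location",
                                     "replicate")])
  if (anyDuplicated(key))
    stop("duplicate (sample, trait, location, replicate) key: ",
         key[duplicated(key)][1])
  summarise <- function(df, by) {
    sp <- split(df$value, df[by], drop = TRUE)
    keys <- do.call(rbind, strsplit(names(sp), "\\."))
    out <- data.frame(keys, stringsAsFactors = FALSE)
    names(out) <- by
    out$n <- vapply(sp, length, 0L)
    out$mean <- vapply(sp, mean, 0)
    out$sd <- vapply(sp, function(x) if (length(x) > 1) stats::sd(x)
                     else NA_real_, 0)
    out$min <- vapply(sp, min, 0)
    out$max <- vapply(sp, max, 0)
    rownames(out) <- NULL
    out
  }
  list(overall = summarise(phenotypes, "trait"),
       by_location = summarise(phenotypes, c("trait", "location")))
}
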
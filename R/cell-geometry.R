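## Cell geometry: volume and surface area from measured dimensions, size
## classification, and prophage burden per unit of cell volume.
##
## Rods are modelled as cylinders (r = width / 2), cocci as spheres
## (r = width / 2), ovoid cells as general ellipsoids with semi-axes
## a = half length and b = c = half width unless given explicitly. The
## ellipsoid surface uses the Knud Thomsen approximation (p = 1.6075),
## which is exact in the spherical limit and within ~1.2% elsewhere.

KNUD_THOMSEN_P <- 1.6075

shape_dims <- function(shape, length_um, width_um, a, b, c) {
  if (is.null(a)) a <- length_um / 2
  if (is.null(b)) b <- width_um / 2
  if (is.null(c)) c <- b
  switch(shape,
         rod    = list(r = width_um / 2, L = length_um),
         coccus = list(r = width_um / 2),
         ovoid  = list(a = a, b = b, c = c))
}

check_pos <- function(...) {
  v <- unlist(list(...))
  if (length(v) == 0L || any(!is.finite(v)) || any(v <= 0)) {
    stop("cell dimensions must be positive", call. = FALSE)
  }
}

#' Cell volume from shape and dimensions
#'
#' Rod: \eqn{V = \pi r^2 L}; coccus: \eqn{V = \frac{4}{3}\pi r^3}; ovoid:
#' \eqn{V = \frac{4}{3}\pi a b c}. The exact 4/3 is used by default;
#' `legacy_constant = TRUE` substitutes the truncated 1.333 for regression
#' against tables computed with that constant (relative error 2.5e-4).
#'
#' @param shape `"rod"`, `"coccus"` or `"ovoid"`.
#' @param length_um,width_um Cell length and width in micrometres
#'   (width only, for cocci).
#' @param a,b,c Optional explicit semi-axes (um) for ovoid cells; default
#'   a = length/2, b = c = width/2.
#' @param legacy_constant Use 1.333 in place of 4/3.
#' @return Volume in um^3.
#' @export
estimate_volume <- function(shape = c("rod", "coccus", "ovoid"),
                            length_um = NULL, width_um = NULL,
                            a = NULL, b = NULL, c = NULL,
                            legacy_constant = FALSE) {
  shape <- match.arg(shape)
  k <- if (legacy_constant) 1.333 else 4 / 3
  d <- shape_dims(shape, length_um, width_um, a, b, c)
  switch(shape,
         rod = {
           check_pos(d$r, d$L)
           pi * d$r^2 * d$L
         },
         coccus = {
           check_pos(d$r)
           k * pi * d$r^3
         },
         ovoid = {
           check_pos(d$a, d$b, d$c)
           k * pi * d$a * d$b * d$c
         })
}

#' Cell surface area from shape and dimensions
#'
#' Coccus: \eqn{A = 4\pi r^2}; rod: closed cylinder
#' \eqn{A = 2\pi r^2 + 2\pi r L}; ovoid: Knud Thomsen approximation
#' \eqn{A \approx 4\pi\left[\frac{(ab)^p + (ac)^p + (bc)^p}{3}\right]^{1/p}}
#' with \eqn{p = 1.6075}, which collapses to the sphere formula when
#' a = b = c.
#'
#' @inheritParams estimate_volume
#' @return Surface area in um^2.
#' @export
estimate_surface_area <- function(shape = c("rod", "coccus", "ovoid"),
                                  length_um = NULL, width_um = NULL,
                                  a = NULL, b = NULL, c = NULL) {
  shape <- match.arg(shape)
  d <- shape_dims(shape, length_um, width_um, a, b, c)
  switch(shape,
         rod = {
           check_pos(d$r, d$L)
           2 * pi * d$r^2 + 2 * pi * d$r * d$L
         },
         coccus = {
           check_pos(d$r)
           4 * pi * d$r^2
         },
         ovoid = {
           check_pos(d$a, d$b, d$c)
           p <- KNUD_THOMSEN_P
           4 * pi * (((d$a * d$b)^p + (d$a * d$c)^p + (d$b * d$c)^p) / 3)^(1 / p)
         })
}

#' Classify cells by volume and surface area
#'
#' Volume bins: small `< 1`, middle `[1, 2.5]`, big `> 2.5` um^3; area bins:
#' small `< 6`, middle `[6, 12]`, large `> 12` um^2. Boundary values fall in
#' the middle class.
#'
#' @param volume Volume(s), um^3.
#' @param area Surface area(s), um^2 (optional).
#' @return Tibble with `volume_class` and (if area given) `area_class`;
#'   NA input gives NA class.
#' @export
classify_cell <- function(volume, area = NULL) {
  bin <- function(x, lo, hi, labels) {
    ifelse(is.na(x), NA_character_,
           ifelse(x < lo, labels[1L],
                  ifelse(x <= hi, labels[2L], labels[3L])))
  }
  out <- tibble::tibble(
    volume_class = bin(volume, 1, 2.5, c("small", "middle", "big")))
  if (!is.null(area)) {
    out$area_class <- bin(area, 6, 12, c("small", "middle", "large"))
  }
  out
}

#' Prophage burden per cell
#'
#' Two complementary burden measures: foreign DNA per unit cell volume
#' (`prophage_bp_per_um3 = total_prophage_bp / volume`) and prophage density
#' (`prophage_density = total_prophage_bp / genome_bp`, identical to the
#' census `prophage_fraction`). Strains with small cells can rank low on the
#' per-volume measure while ranking high on density, which is why both are
#' reported.
#'
#' @param census_row One-row census fragment (from [genome_burden()] or
#'   [strain_census()]): needs `total_prophage_bp`, `genome_bp`,
#'   `n_prophages`.
#' @param volume_um3 Cell volume; `NA` marks the per-volume measure
#'   unavailable (never coerced to zero).
#' @return One-row tibble: `prophage_bp_per_um3, prophage_density,
#'   n_prophages_per_cell`.
#' @export
burden_per_cell <- function(census_row, volume_um3) {
  stopifnot(nrow(census_row) == 1L)
  if (!is.na(volume_um3) && volume_um3 <= 0) {
    stop("volume must be > 0", call. = FALSE)
  }
  tibble::tibble(
    prophage_bp_per_um3 = if (is.na(volume_um3)) NA_real_ else
      census_row$total_prophage_bp / volume_um3,
    prophage_density = census_row$total_prophage_bp / census_row$genome_bp,
    n_prophages_per_cell = census_row$n_prophages
  )
}

#' Add geometry columns to a trait table
#'
#' Fills `volume_um3` and `area_um2` from shape and dimensions where absent
#' (measured values are kept), then adds `volume_class`/`area_class`.
#'
#' @param traits Trait tibble ([read_trait_table()]).
#' @param legacy_constant Passed to [estimate_volume()].
#' @return The augmented tibble.
#' @export
add_geometry <- function(traits, legacy_constant = FALSE) {
  if (!"volume_um3" %in% names(traits)) traits$volume_um3 <- NA_real_
  if (!"area_um2" %in% names(traits)) traits$area_um2 <- NA_real_
  for (i in seq_len(nrow(traits))) {
    sh <- traits$shape[i]
    if (is.na(sh) || !sh %in% c("rod", "coccus", "ovoid")) next
    ok_dims <- !is.na(traits$width_um[i]) &&
      (sh == "coccus" || !is.na(traits$length_um[i]))
    if (!ok_dims) next
    if (is.na(traits$volume_um3[i])) {
      traits$volume_um3[i] <- estimate_volume(
        sh, length_um = traits$length_um[i], width_um = traits$width_um[i],
        legacy_constant = legacy_constant)
    }
    if (is.na(traits$area_um2[i])) {
      traits$area_um2[i] <- estimate_surface_area(
        sh, length_um = traits$length_um[i], width_um = traits$width_um[i])
    }
  }
  cls <- classify_cell(traits$volume_um3, traits$area_um2)
  traits$volume_class <- cls$volume_class
  traits$area_class <- cls$area_class
  traits
}
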
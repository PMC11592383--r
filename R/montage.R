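#' The 21 canonical electrode sites of the international 10-20 system
#'
#' Returns the ordered site names used throughout the package: the 19 scalp
#' positions of the 10-20 montage plus the two ear (auricular) references
#' A1/A2. Channel selection, detection matrices and topographic rendering all
#' use this order.
#'
#' @return Character vector of 21 site names.
#' @export
#' @examples
#' canonical_sites()
canonical_sites <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "A1", "A2", "Fz", "Cz", "Pz")
}

#' Hemisphere tag for a 10-20 site name
#'
#' Follows the 10-20 convention: odd terminal digit = left hemisphere, even =
#' right, a terminal "z" = midline. The ear sites A1/A2 carry left/right tags
#' like scalp sites.
#'
#' @param site Character vector of site names.
#' @return Character vector: "left", "right" or "midline".
#' @export
site_hemisphere <- function(site) {
  last <- substr(site, nchar(site), nchar(site))
  out <- character(length(site))
  out[tolower(last) == "z"] <- "midline"
  digit <- suppressWarnings(as.integer(last))
  out[!is.na(digit) & digit %% 2L == 1L] <- "left"
  out[!is.na(digit) & digit %% 2L == 0L] <- "right"
  if (any(out == "")) {
    stop("cannot determine hemisphere for site(s): ",
         paste(site[out == ""], collapse = ", "), call. = FALSE)
  }
  out
}

#' Schematic 10-20 electrode layout on the unit head disc
#'
#' Two-dimensional schematic coordinates (nose up, left hemisphere at
#' negative x) for the 21 canonical sites, with hemisphere tags. These are
#' drawing positions for topographic maps, not digitized 3-D electrode
#' locations.
#'
#' @return A tibble with columns `site`, `x`, `y`, `hemisphere`.
#' @export
#' @examples
#' electrode_layout()
electrode_layout <- function() {
  # perimeter sites on a 0.9-radius ring, ears just outside the head circle
  ring <- function(deg, r = 0.9) c(x = r * sinpi(deg / 180), y = r * cospi(deg / 180))
  pos <- rbind(
    Fp1 = ring(-18), Fp2 = ring(18),
    F7  = ring(-54), F8  = ring(54),
    T3  = ring(-90), T4  = ring(90),
    T5  = ring(-126), T6 = ring(126),
    O1  = ring(-162), O2 = ring(162),
    A1  = c(-1.08, 0), A2 = c(1.08, 0),
    F3  = c(-0.36, 0.45), F4 = c(0.36, 0.45),
    C3  = c(-0.45, 0), C4 = c(0.45, 0),
    P3  = c(-0.36, -0.45), P4 = c(0.36, -0.45),
    Fz  = c(0, 0.45), Cz = c(0, 0), Pz = c(0, -0.45)
  )
  sites <- canonical_sites()
  tibble::tibble(
    site = sites,
    x = pos[sites, 1],
    y = pos[sites, 2],
    hemisphere = site_hemisphere(sites)
  )
}

#' Normalize an EDF channel label to its canonical 10-20 site name
#'
#' EDF label dialects vary ("EEG Fp1-Ref", "FP1-LE", ...). This strips a
#' leading "EEG " prefix and a "-Ref"/"-REF"/"-LE" suffix, trims whitespace,
#' and matches case-insensitively against the 21 canonical names. Labels that
#' do not match any canonical site are returned cleaned but otherwise
#' unchanged (so non-EEG channels such as ECG keep a recognizable name).
#'
#' @param label Character vector of raw channel labels.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_channel_name(c("EEG Fp1-Ref", "FP2-LE", "ECG"))
normalize_channel_name <- function(label) {
  x <- trimws(label)
  x <- sub("^EEG[ _]+", "", x, ignore.case = TRUE)
  x <- sub("-(Ref|REF|LE)$", "", x, ignore.case = TRUE)
  x <- trimws(x)
  canon <- canonical_sites()
  idx <- match(tolower(x), tolower(canon))
  ifelse(is.na(idx), x, canon[idx])
}
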
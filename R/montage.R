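#' Schematic 10-20 / 10-10 montage coordinates
#'
#' Returns approximate 2D scalp coordinates (top view, nose up, unit head
#' radius) for standard 10-20 / 10-10 electrode labels. The layout is
#' schematic: anterior-posterior rows at fixed y, lateral positions at fixed
#' |x| per numeral. It is used to parameterize spatial component templates
#' (Gaussian bumps, hemispheric mirroring) in the synthetic cohort generator
#' and for left/right bookkeeping; no source modelling is attempted.
#'
#' @param labels character vector of electrode labels (e.g., `"PO7"`, `"Cz"`).
#' @return data.frame with columns `label`, `x` (left negative), `y`
#'   (anterior positive). Unknown labels raise an error.
#' @export
montage_positions <- function(labels) {
  rows <- c(Fp = 0.90, AF = 0.70, F = 0.50, FT = 0.30, FC = 0.25,
            T = 0.00, C = 0.00, TP = -0.25, CP = -0.25, P = -0.50,
            PO = -0.70, O = -0.90, I = -1.00)
  colx <- c("1" = -0.20, "2" = 0.20, "3" = -0.40, "4" = 0.40,
            "5" = -0.60, "6" = 0.60, "7" = -0.80, "8" = 0.80,
            "9" = -0.95, "10" = 0.95, z = 0)
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^(Fp|AF|FT|FC|TP|CP|PO|F|T|C|P|O|I)(z|[0-9]+)$", lab))[[1]]
    if (length(m) == 0) stop("unknown electrode label: ", lab)
    pre <- m[2]; suf <- m[3]
    if (!suf %in% names(colx)) stop("unknown electrode label: ", lab)
    x <- unname(colx[suf])
    # T7/T8 sit on the C row at |x| = 0.8 in the 10-10 nomenclature
    if (pre == "T") x <- sign(x) * 0.80
    if (pre %in% c("FT", "TP") && abs(x) < 0.8 && suf %in% c("7", "8")) x <- sign(x) * 0.80
    if (pre == "Fp") x <- sign(x) * 0.25
    c(x = x, y = unname(rows[pre]))
  }
  eog <- labels %in% c("HEOG", "VEOG")
  xy <- matrix(NA_real_, length(labels), 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_along(labels)) {
    if (eog[i]) {
      xy[i, ] <- if (labels[i] == "HEOG") c(-1.1, 0.95) else c(0.35, 1.05)
    } else {
      xy[i, ] <- parse_one(labels[i])
    }
  }
  data.frame(label = labels, x = xy[, "x"], y = xy[, "y"], stringsAsFactors = FALSE)
}

#' Default EEG channel sets
#'
#' Ordered master list of 10-20 / 10-10 labels. The first 30 labels form the
#' default reduced montage (includes the frontal eye-proxy pair F7/F8 and the
#' 3-channel posterior N1 regions of interest); the full list of 60 matches a
#' denser recording layout with 7-channel posterior ROIs.
#'
#' @param n number of EEG channels requested (2..60).
#' @return character vector of `n` labels.
#' @export
montage_labels <- function(n = 30) {
  master <- c(
    # core 30-channel set
    "Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "FC5", "FC6", "FC1",
    "FC2", "FCz", "T7", "T8", "C3", "C4", "Cz", "CP5", "CP6", "CP1",
    "CP2", "P7", "P8", "P3", "P4", "Pz", "O1", "O2", "Oz", "POz",
    # extension to 60 channels
    "AF3", "AF4", "AF7", "AF8", "F1", "F2", "F5", "F6", "FT7", "FT8",
    "FC3", "FC4", "C1", "C2", "C5", "C6", "CP3", "CP4", "CPz", "TP7",
    "TP8", "P1", "P2", "P5", "P6", "PO3", "PO4", "PO7", "PO8", "Fpz")
  n <- as.integer(n)
  if (n < 2 || n > length(master)) stop("n must be between 2 and ", length(master))
  master[seq_len(n)]
}

# Mirror a label across the midline (odd <-> even numerals); z labels map to
# themselves.
mirror_label <- function(labels) {
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) == 0 || m[3] == "z") return(lab)
    k <- as.integer(m[3])
    paste0(m[2], if (k %% 2 == 1) k + 1 else k - 1)
  }, character(1), USE.NAMES = FALSE)
}

# Unit-norm spatial template: sum of Gaussian bumps over the montage.
# centers: matrix with columns x, y; widths and signs recycled.
gaussian_template <- function(positions, centers, widths = 0.35, signs = 1) {
  centers <- rbind(centers)
  widths <- rep_len(widths, nrow(centers))
  signs <- rep_len(signs, nrow(centers))
  v <- numeric(nrow(positions))
  for (i in seq_len(nrow(centers))) {
    d2 <- (positions$x - centers[i, 1])^2 + (positions$y - centers[i, 2])^2
    v <- v + signs[i] * exp(-d2 / (2 * widths[i]^2))
  }
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
}
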
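.sn_cache <- new.env(parent = emptyenv())

#' Desikan-Killiany ROI table
#'
#' The packaged 68-region cortical parcellation used as network nodes.
#' ROI numbers are 1-based; even numbers are left-hemisphere regions and odd
#' numbers right-hemisphere regions, with ROIs 1-20 covering the frontal lobe.
#' Lobe categories are frontal, temporal, parietal, occipital, isthmus
#' (the isthmus cingulate, outside the four lobes) and other (midline
#' cingulate/insular regions).
#'
#' @return data.frame with columns `roi`, `name`, `hemisphere`, `lobe`.
#' @export
dk_roi_table <- function() {
  if (is.null(.sn_cache$dk)) {
    path <- system.file("extdata", "dk_rois.csv", package = "strokenet")
    .sn_cache$dk <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .sn_cache$dk
}

#' Hemisphere of an ROI number
#' @param roi integer ROI number(s) in 1..68.
#' @return "left" for even numbers, "right" for odd.
#' @export
roi_hemisphere <- function(roi) ifelse(roi %% 2 == 0, "left", "right")

roi_lobe <- function(roi, table = dk_roi_table()) {
  table$lobe[match(roi, table$roi)]
}

#' Standard 19-channel 10-20 montage labels
#' @return character vector of 19 labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Left/right/midline from the 10-20 convention: odd digit = left, even = right.
channel_hemisphere <- function(labels) {
  digit <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  out <- ifelse(is.na(digit), "midline", ifelse(digit %% 2 == 1, "left", "right"))
  out
}
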
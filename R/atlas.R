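# Desikan-Killiany atlas ID conventions.
#
# Region IDs 1..68 follow the alphabetical ordering of the 34 DK region
# names, with the left hemisphere taking the odd ID 2a-1 and the right
# hemisphere the even ID 2a, where a is the 1-based alphabetical rank.
# The source study never prints its full ID table; this rule is a
# reconstruction that reproduces every (id, name, hemisphere) triple it does
# print, and it can be overridden with a user-supplied atlas table.

DK_REGIONS <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")

#' Desikan-Killiany atlas map
#'
#' Returns the mapping from ROI id (1..68) to cortical region name and
#' hemisphere. IDs are assigned alphabetically over the 34 bilateral
#' Desikan-Killiany regions: the region with alphabetical rank `a` gets id
#' `2a - 1` on the left hemisphere and `2a` on the right. This ordering is a
#' documented reconstruction (the rule reproduces all id/name/hemisphere
#' triples published alongside the method); supply your own table to
#' [read_cohort()] if your parcellation uses different ids.
#'
#' @param n_roi number of ROI ids to return (default 68; smaller values take
#'   the leading ids, which is what reduced-scale synthetic cohorts use).
#' @return A data.frame with columns `roi`, `region`, `hemisphere`.
#' @examples
#' head(dk_atlas())
#' dk_atlas()[8, ]  # cuneus R
#' @export
dk_atlas <- function(n_roi = 68L) {
  stopifnot(n_roi >= 1, n_roi <= 68)
  df <- data.frame(
    roi = seq_len(68L),
    region = rep(DK_REGIONS, each = 2L),
    hemisphere = rep(c("L", "R"), times = 34L),
    stringsAsFactors = FALSE)
  df[seq_len(n_roi), , drop = FALSE]
}

#' Look up an ROI id in the atlas
#'
#' @param roi_id integer ROI id in 1..68.
#' @param atlas atlas data.frame as returned by [dk_atlas()].
#' @return Named character vector with elements `region` and `hemisphere`.
#' @examples
#' roi_name(8)   # cuneus R
#' roi_name(63)  # supramarginal L
#' @export
roi_name <- function(roi_id, atlas = dk_atlas()) {
  if (length(roi_id) != 1L || !is.finite(roi_id) || roi_id != round(roi_id))
    stop("roi_id must be a single integer")
  if (roi_id < 1 || roi_id > nrow(atlas))
    stop("roi_id ", roi_id, " outside 1..", nrow(atlas))
  row <- atlas[atlas$roi == roi_id, ]
  c(region = row$region, hemisphere = row$hemisphere)
}
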
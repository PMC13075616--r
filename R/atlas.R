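#' Cortical + medial temporal parcellation table
#'
#' Returns the packaged region table used throughout the pipeline: the 34
#' Desikan-Killiany cortical labels per hemisphere plus hippocampus and
#' amygdala bilaterally (basal ganglia, thalamus, brainstem and cerebellum
#' are not part of the table), i.e. 72 regions of interest in total.
#'
#' @param space Label namespace: `"lr"` gives anatomical left/right labels
#'   (`"lh.hippocampus"`); `"ipsicontra"` gives labels relative to the
#'   discharge-generating hemisphere after hemisphere swapping
#'   (`"Hippocampus_ipsi"`), with `ipsi` mapped onto the right-hemisphere
#'   slot by convention.
#' @return A data.frame with columns `label` (full unique label),
#'   `region` (base region name) and `hemisphere` (`"L"`/`"R"` or
#'   `"ipsi"`/`"contra"`).
#' @examples
#' nrow(load_atlas())  # 72
#' @export
load_atlas <- function(space = c("ipsicontra", "lr")) {
  space <- match.arg(space)
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal",
    "hippocampus", "amygdala"
  )
  region <- rep(regions, times = 2)
  if (space == "lr") {
    hemisphere <- rep(c("L", "R"), each = length(regions))
    label <- paste0(ifelse(hemisphere == "L", "lh.", "rh."), region)
  } else {
    hemisphere <- rep(c("contra", "ipsi"), each = length(regions))
    label <- paste0(cap1(region), "_", hemisphere)
  }
  at <- data.frame(label = label, region = region, hemisphere = hemisphere,
                   stringsAsFactors = FALSE)
  stopifnot(nrow(at) == 72L, !anyDuplicated(at$label))
  at
}

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Swap hemispheres so the discharge side reads as ipsilateral
#'
#' Patients whose selected discharges originate in the left hemisphere have
#' their left/right labels exchanged so that, across patients, "ipsi" always
#' denotes the hemisphere generating the marked discharges. For right-sided
#' patients the mapping is the identity. Applying the swap twice restores
#' the input.
#'
#' @param x A character vector of `"lh."`/`"rh."`-prefixed labels, or a
#'   matrix whose dimnames carry such labels.
#' @param ied_side `"left"` or `"right"`: hemisphere generating the
#'   discharges.
#' @return Object of the same shape with labels exchanged when
#'   `ied_side == "left"`.
#' @export
hemisphere_swap <- function(x, ied_side = c("right", "left")) {
  ied_side <- match.arg(ied_side)
  if (is.matrix(x)) {
    rownames(x) <- hemisphere_swap(rownames(x), ied_side)
    colnames(x) <- hemisphere_swap(colnames(x), ied_side)
    return(x)
  }
  if (ied_side == "right") return(x)
  swapped <- x
  is_l <- startsWith(x, "lh.")
  is_r <- startsWith(x, "rh.")
  if (any(!(is_l | is_r))) {
    stop("unpaired label(s): ", paste(x[!(is_l | is_r)], collapse = ", "))
  }
  swapped[is_l] <- sub("^lh\\.", "rh.", x[is_l])
  swapped[is_r] <- sub("^rh\\.", "lh.", x[is_r])
  swapped
}

#' Convert left/right labels to ipsi/contra labels
#'
#' After [hemisphere_swap()] the right hemisphere holds the discharge side;
#' this relabels `"rh."` as `"_ipsi"` and `"lh."` as `"_contra"` in the
#' namespace used by the synthetic generator and the group-level tables.
#'
#' @param labels Character vector of `"lh."`/`"rh."` labels.
#' @return Character vector of `"<Region>_ipsi"` / `"<Region>_contra"` labels.
#' @export
to_ipsicontra <- function(labels) {
  region <- sub("^(lh|rh)\\.", "", labels)
  side <- ifelse(startsWith(labels, "rh."), "ipsi", "contra")
  paste0(cap1(region), "_", side)
}
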
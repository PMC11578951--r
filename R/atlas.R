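# AAL-90 parcellation bookkeeping. Node order follows the standard atlas
# numbering: 45 bilateral structures, left hemisphere on odd indices.

.aal90_base <- c(
  "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
  "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
  "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
  "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
  "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
  "MTG", "TPOmid", "ITG"
)

#' AAL-90 atlas label table
#'
#' Returns the 90-region automated anatomical labeling (AAL) parcellation
#' used as network nodes, in the standard atlas ordering (left/right
#' interleaved, left first).
#'
#' @return A data frame with columns `index` (1-90), `region`
#'   (abbreviated structure name, e.g. `"THA"`), `hemisphere`
#'   (`"L"`/`"R"`) and `label` (`"THA.L"` style, used as node labels
#'   throughout the package).
#' @export
#' @examples
#' head(aal90_atlas())
aal90_atlas <- function() {
  region <- rep(.aal90_base, each = 2L)
  hemisphere <- rep(c("L", "R"), times = length(.aal90_base))
  data.frame(
    index = seq_len(90L),
    region = region,
    hemisphere = hemisphere,
    label = paste(region, hemisphere, sep = "."),
    stringsAsFactors = FALSE
  )
}

#' AAL-90 node labels
#'
#' @return Character vector of 90 labels such as `"PreCG.L"`.
#' @export
aal90_labels <- function() aal90_atlas()$label

#' Atlas indices for a set of structures
#'
#' @param regions Character vector of abbreviated structure names
#'   (e.g. `c("CAU", "PUT")`).
#' @param hemisphere `"both"`, `"L"` or `"R"`.
#' @return Integer vector of node indices in atlas order.
#' @export
aal90_indices <- function(regions, hemisphere = "both") {
  atlas <- aal90_atlas()
  bad <- setdiff(regions, atlas$region)
  if (length(bad) > 0L) {
    stop("unknown atlas structure(s): ", paste(bad, collapse = ", "))
  }
  keep <- atlas$region %in% regions
  if (hemisphere != "both") keep <- keep & atlas$hemisphere == hemisphere
  atlas$index[keep]
}

# Basal-ganglia / thalamic / sensorimotor slots perturbed by default in the
# synthetic disease model (striato-pallido-thalamo-cortical motor loop).
.default_perturbed_regions <- c("CAU", "PUT", "PAL", "THA", "PoCG")

# The eight a-priori motor structures screened for outcome correlations.
.motor_roi_regions <- c(
  "CAU", "PUT", "PAL", "THA", "PreCG", "PoCG", "SMA", "PCL"
)
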
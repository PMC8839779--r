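#' The 14 facial regions of interest
#'
#' Canonical ROI identifiers used throughout the package: nose tip, central /
#' right / left forehead, right / left cheek, nasal septum, central / right /
#' left chin, right / left periorbital and right / left maxillary regions.
#'
#' @return character vector of length 14.
#' @export
roi_names <- function() {
  c("Nose", "Forehead", "R-Forehead", "L-Forehead", "R-Cheek", "L-Cheek",
    "N-Sept", "Chin", "R-Chin", "L-Chin", "R-POrb", "L-POrb", "R-Max", "L-Max")
}

# Display labels used in feature-column names ("RPOrb", "N-Sept", ...):
# hyphens dropped except for the nasal septum, whose conventional label
# keeps it.
roi_label <- function(name) ifelse(name == "N-Sept", name, gsub("-", "", name))

thermal_feature_names <- function() {
  as.vector(t(outer(roi_label(roi_names()), c("Mean", "Std", "DMean", "DStd"),
                    paste)))
}

eda_feature_names <- function() {
  c("TonicMean", "TonicStd", "PksMax", "PhasicMean", "PhasicStd",
    "NPks", "PksSum", "EDAsymp")
}

hrv_feature_names <- function() {
  c("mean HRV", "std HRV", "RMSSD", "pNN50", "LF", "HF", "LF/HF",
    "SD1", "SD2", "SampEn")
}

resp_feature_names <- function() "RESP freq"

#' Feature-column names of the assembled feature table
#' @param set `"full"`, `"thermo"` or `"nothermo"`.
#' @return character vector (56, 56, or 19 names).
#' @export
feature_names <- function(set = c("full", "thermo", "nothermo")) {
  set <- match.arg(set)
  thermo <- thermal_feature_names()
  other <- c(eda_feature_names(), hrv_feature_names(), resp_feature_names())
  switch(set, full = c(thermo, other), thermo = thermo, nothermo = other)
}
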
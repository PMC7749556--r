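#' Default white-matter tract list (54 parcels)
#'
#' A left/right parcellation of 27 major white-matter structures modeled on
#' the Johns Hopkins University DTI-based atlas nomenclature, giving the 54
#' seed parcels the analysis iterates over. Parcel ids are the positions in
#' this vector (1..54). The list is a stand-in naming scheme for synthetic
#' label volumes; a real atlas label volume with its own ids may be
#' supplied instead wherever labels are consumed.
#'
#' @return Character vector of 54 tract names, including `"body_cc_L"` and
#'   `"body_cc_R"`.
#' @export
jhu_tract_names <- function() {
  structures <- c(
    "genu_cc", "body_cc", "splenium_cc",
    "cingulum_cingulate", "cingulum_hippocampal",
    "fornix", "corticospinal_tract", "medial_lemniscus",
    "inferior_cerebellar_peduncle", "superior_cerebellar_peduncle",
    "cerebral_peduncle", "anterior_limb_internal_capsule",
    "posterior_limb_internal_capsule", "retrolenticular_internal_capsule",
    "anterior_corona_radiata", "superior_corona_radiata",
    "posterior_corona_radiata", "posterior_thalamic_radiation",
    "sagittal_stratum", "external_capsule",
    "superior_longitudinal_fasciculus", "inferior_longitudinal_fasciculus",
    "superior_fronto_occipital_fasciculus",
    "inferior_fronto_occipital_fasciculus",
    "uncinate_fasciculus", "tapetum", "corticopontine_tract")
  as.vector(t(outer(structures, c("L", "R"), paste, sep = "_")))
}
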
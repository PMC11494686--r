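#' @useDynLib hopfec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd qt pt rnorm runif rbinom setNames coef lm
#'   residuals fitted simulate t.test median
#' @importFrom utils read.table write.table head
NULL

# The 180 cortical region labels of the HCP-MMP surface parcellation,
# in the standard Glasser index order (1..180). Each label exists in
# both hemispheres, giving the 360-region full scheme.
hcpmmp_labels <- c(
  "V1", "MST", "V6", "V2", "V3", "V4", "V8", "4", "3b", "FEF",
  "PEF", "55b", "V3A", "RSC", "POS2", "V7", "IPS1", "FFC", "V3B", "LO1",
  "LO2", "PIT", "MT", "A1", "PSL", "SFL", "PCV", "STV", "7Pm", "7m",
  "POS1", "23d", "v23ab", "d23ab", "31pv", "5m", "5mv", "23c", "5L", "24dd",
  "24dv", "7AL", "SCEF", "6ma", "7Am", "7PL", "7PC", "LIPv", "VIP", "MIP",
  "1", "2", "3a", "6d", "6mp", "6v", "p24pr", "33pr", "a24pr", "p32pr",
  "a24", "d32", "8BM", "p32", "10r", "47m", "8Av", "8Ad", "9m", "8BL",
  "9p", "10d", "8C", "44", "45", "47l", "a47r", "6r", "IFJa", "IFJp",
  "IFSp", "IFSa", "p9-46v", "46", "a9-46v", "9-46d", "9a", "10v", "a10p", "10pp",
  "11l", "13l", "OFC", "47s", "LIPd", "6a", "i6-8", "s6-8", "43", "OP4",
  "OP1", "OP2-3", "52", "RI", "PFcm", "PoI2", "TA2", "FOP4", "MI", "Pir",
  "AVI", "AAIC", "FOP1", "FOP3", "FOP2", "PFt", "AIP", "EC", "PreS", "H",
  "ProS", "PeEc", "STGa", "PBelt", "A5", "PHA1", "PHA3", "STSda", "STSdp", "STSvp",
  "TGd", "TE1a", "TE1p", "TE2a", "TF", "TE2p", "PHT", "PH", "TPOJ1", "TPOJ2",
  "TPOJ3", "DVT", "PGp", "IP2", "IP1", "IP0", "PFop", "PF", "PFm", "PGi",
  "PGs", "V6A", "VMV1", "VMV3", "V4t", "FST", "V3CD", "LO3", "VMV2", "31pd",
  "31a", "VVC", "25", "s32", "pOFC", "PoI1", "Ig", "FOP5", "p10p", "p47r",
  "TGv", "MBelt", "LBelt", "A4", "STSva", "TE1m", "PI", "a32pr", "p24", "PHA2")

# Coarse processing-stream tags for the `group` metadata column.
region_group <- function(label) {
  groups <- list(
    "early visual"            = c("V1", "V2", "V3", "V4", "V3A", "V3B",
                                  "V3CD", "V6", "V6A", "V7", "V8"),
    "ventromedial visual"     = c("VMV1", "VMV2", "VMV3", "VVC"),
    "ventrolateral visual"    = c("FFC", "PIT", "TE2p", "TE1p", "TE2a", "PH",
                                  "PHT"),
    "hippocampal system"      = c("H", "PreS", "EC", "PeEc", "TF",
                                  "PHA1", "PHA2", "PHA3", "ProS", "RSC"),
    "lateral temporal semantic" = c("STGa", "STSda", "STSdp", "STSva",
                                    "STSvp", "TGd", "TGv", "PSL"),
    "inferior frontal language" = c("44", "45", "47l", "IFJa", "IFJp",
                                    "IFSp", "IFSa"),
    "orbitofrontal-vmPFC reward" = c("d32", "p24", "pOFC", "s32", "10d",
                                     "10pp", "11l", "a10p", "OFC", "p10p",
                                     "10r", "10v", "13l", "25", "p32", "a24"),
    "intraparietal"           = c("LIPv", "LIPd", "MIP", "VIP", "AIP",
                                  "IPS1", "IP0", "IP1", "IP2"))
  for (g in names(groups)) if (label %in% groups[[g]]) return(g)
  "other"
}

#' Load a parcellation scheme from a region metadata table
#'
#' A parcellation scheme is the ordered frame for every table and matrix in
#' the package: a set of region labels, each present once per hemisphere.
#'
#' @param metadata A data frame with columns `index`, `label`, `hemisphere`
#'   (`"L"` or `"R"`) and optionally `group`, or the path of a TSV file with
#'   those columns. Defaults to the packaged 360-region HCP-MMP table.
#' @return An object of class `"parcellation"`: a list with `regions`
#'   (data frame ordered by `index`), `n_regions` and `n_per_hemisphere`.
#' @examples
#' sch <- load_parcellation()
#' sch$n_regions
#' @export
load_parcellation <- function(metadata = NULL) {
  if (is.null(metadata))
    metadata <- system.file("extdata", "hcpmmp360.tsv", package = "hopfec")
  if (is.character(metadata)) {
    metadata <- read.table(metadata, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character",
                                          "character", "character"),
                           quote = "", comment.char = "")
  }
  req <- c("index", "label", "hemisphere")
  if (!all(req %in% names(metadata)))
    stop("region metadata must have columns: ", paste(req, collapse = ", "))
  if (!"group" %in% names(metadata)) metadata$group <- "other"
  metadata <- metadata[order(metadata$index),
                       c("index", "label", "hemisphere", "group")]
  rownames(metadata) <- NULL
  bad <- setdiff(unique(metadata$hemisphere), c("L", "R"))
  if (length(bad))
    stop("unknown hemisphere code: ", paste(bad, collapse = ", "))
  for (h in c("L", "R")) {
    lab <- metadata$label[metadata$hemisphere == h]
    if (anyDuplicated(lab))
      stop("duplicate label within hemisphere ", h, ": ",
           paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  labL <- metadata$label[metadata$hemisphere == "L"]
  labR <- metadata$label[metadata$hemisphere == "R"]
  unpaired <- c(setdiff(labL, labR), setdiff(labR, labL))
  if (length(unpaired))
    stop("label(s) not present in both hemispheres: ",
         paste(unpaired, collapse = ", "))
  structure(list(regions = metadata,
                 n_regions = nrow(metadata),
                 n_per_hemisphere = nrow(metadata) / 2L),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation scheme:", x$n_regions, "regions (",
      x$n_per_hemisphere, "per hemisphere )\n")
  cat("First labels:",
      paste(head(scheme_labels(x), 6), collapse = ", "), "...\n")
  invisible(x)
}

#' Full labels (label_hemisphere) of a scheme, in scheme order
#' @param scheme A `"parcellation"` object.
#' @return Character vector like `"V1_L"`, length `n_regions`.
#' @export
scheme_labels <- function(scheme) {
  paste(scheme$regions$label, scheme$regions$hemisphere, sep = "_")
}

#' Reduced parcellation keeping hemisphere pairing
#'
#' Subsets the full scheme to the given (hemisphere-less) labels, keeping
#' both hemispheres of each so that laterality operations stay defined.
#' Useful for desk-scale analyses and simulation studies.
#'
#' @param labels Character vector of region labels (no hemisphere suffix).
#' @param scheme Base scheme to subset; default the packaged full scheme.
#' @return A `"parcellation"` object with `2 * length(labels)` regions.
#' @export
reduced_scheme <- function(labels, scheme = load_parcellation()) {
  missing_lab <- setdiff(labels, scheme$regions$label)
  if (length(missing_lab))
    stop("label(s) not in scheme: ", paste(missing_lab, collapse = ", "))
  keep <- scheme$regions[scheme$regions$label %in% labels, ]
  # order: all L in requested order, then all R
  keep <- keep[order(match(keep$hemisphere, c("L", "R")),
                     match(keep$label, labels)), ]
  keep$index <- seq_len(nrow(keep))
  load_parcellation(keep)
}

#' A-priori regions of interest for the episodic-memory contrasts
#'
#' Returns the five hypothesis-driven ROI sets used by the contrast
#' battery: the ventromedial visual "scene" stream, the lateral temporal
#' semantic system, Broca's area, the orbitofrontal/vmPFC/pregenual
#' cingulate reward system, and intraparietal regions.
#'
#' @param scheme Scheme in which every label must resolve.
#' @return Named list of `"roi_set"` objects, each with `name`, `labels`,
#'   and `hemisphere_scope`.
#' @examples
#' rois <- memory_roi_sets()
#' length(rois$scene$labels)  # 7
#' @export
memory_roi_sets <- function(scheme = load_parcellation()) {
  sets <- canonical_roi_labels()
  out <- lapply(names(sets), function(nm)
    roi_set(nm, sets[[nm]], scheme = scheme))
  names(out) <- names(sets)
  out
}

# Canonical label lists of the a-priori ROI sets (full-scheme labels).
canonical_roi_labels <- function() {
  list(
    scene         = c("VMV1", "VMV2", "VMV3", "VVC", "PHA1", "PHA2", "PHA3"),
    semantic      = c("STGa", "STSda", "STSdp", "STSvp", "TGd", "TGv", "PSL"),
    broca         = c("44", "45", "47l"),
    reward        = c("d32", "p24", "pOFC", "s32", "10d", "10pp", "11l",
                      "a10p", "OFC", "p10p"),
    intraparietal = c("LIPv", "MIP", "VIP"))
}

#' Construct an ROI set
#' @param name Identifier.
#' @param labels Region labels (no hemisphere suffix).
#' @param hemisphere_scope `"both"`, `"L"` or `"R"`.
#' @param scheme Scheme the labels must resolve in.
#' @return A `"roi_set"` object.
#' @export
roi_set <- function(name, labels, hemisphere_scope = "both",
                    scheme = load_parcellation()) {
  hemisphere_scope <- match.arg(hemisphere_scope, c("both", "L", "R"))
  missing_lab <- setdiff(labels, scheme$regions$label)
  if (length(missing_lab))
    stop("ROI '", name, "': label(s) not in scheme: ",
         paste(missing_lab, collapse = ", "))
  structure(list(name = name, labels = labels,
                 hemisphere_scope = hemisphere_scope),
            class = "roi_set")
}

#' Region indices covered by an ROI set under a scheme
#' @param roi A `"roi_set"`.
#' @param scheme A `"parcellation"`.
#' @param hemisphere Optional scope override (`"both"`, `"L"`, `"R"`).
#' @return Integer vector of positions in scheme order.
#' @export
roi_indices <- function(roi, scheme, hemisphere = NULL) {
  scope <- if (is.null(hemisphere)) roi$hemisphere_scope else hemisphere
  r <- scheme$regions
  sel <- r$label %in% roi$labels
  if (scope != "both") sel <- sel & r$hemisphere == scope
  idx <- which(sel)
  if (!length(idx))
    stop("ROI '", roi$name, "' resolves to no regions under scope ", scope)
  idx
}
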
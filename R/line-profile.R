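#' @include pathway-model.R
NULL

.hormonePanel <- c("trans_zeatin", "zeatin_riboside", "iP", "GA1", "GA3",
                   "GA4", "IAA", "ABA", "salicylic_acid", "jasmonic_acid",
                   "ACC")

.phenotypeNames <- c("height", "leaves", "leaf_length", "leaf_width",
                     "chlorophyll")

#' Construct a line profile
#'
#' @param lineId line identifier.
#' @param variant the line's variant (\code{WT}, \code{I}, \code{II},
#'   \code{III}).
#' @param expressionRatio named numeric vector of per-gene expression ratios
#'   relative to the wild type; exogenous genes absent from the variant must
#'   be 0 (and are filled in as 0 when missing).
#' @param hormones either a data.frame with columns \code{hormone},
#'   \code{level}, \code{belowDetection}, or a named numeric vector of levels
#'   (then nothing is censored).
#' @param phenotype named numeric vector (\code{height}, \code{leaves},
#'   \code{leaf_length}, \code{leaf_width}, \code{chlorophyll}); missing
#'   entries are NA.
#' @return a \linkS4class{LineProfile}.
#' @export
lineProfile <- function(lineId, variant, expressionRatio,
                        hormones = data.frame(hormone = character(0),
                                              level = numeric(0),
                                              belowDetection = logical(0)),
                        phenotype = numeric(0)) {
  er <- unlist(expressionRatio)
  absent <- setdiff(.exogenousGenes, c(names(er), .variantExogenous(variant)))
  er[absent] <- 0
  if (is.numeric(hormones) && !is.null(names(hormones)))
    hormones <- data.frame(hormone = names(hormones),
                           level = as.numeric(hormones),
                           belowDetection = FALSE)
  ph <- stats::setNames(rep(NA_real_, length(.phenotypeNames)), .phenotypeNames)
  ph[names(phenotype)] <- unlist(phenotype)
  new("LineProfile", lineId = as.character(lineId), variant = variant,
      expressionRatio = er, hormones = hormones, phenotype = ph)
}

#' Personalize a model with a line's expression profile
#'
#' Implements the proportionality assumption between gene expression and
#' enzyme activity: for every gene-tagged reaction the saturation rate
#' constant V is multiplied by the line's expression ratio for that gene.
#' Untagged reactions (compartment exchanges and sinks) are untouched; an
#' exogenous-gene ratio of 0 silences the corresponding ectopic reaction.
#'
#' @param model a \linkS4class{PathwayModel}.
#' @param line a \linkS4class{LineProfile} of the same variant.
#' @return the personalized \linkS4class{PathwayModel}.
#' @examples
#' m <- buildVariantModel("I")
#' ln <- lineProfile("L1", "I", c(tHMGR = 2))
#' # only the plastid HMGR V is doubled
#' @export
scaleLine <- function(model, line) {
  stopifnot(is(model, "PathwayModel"), is(line, "LineProfile"))
  if (line@variant != model@variant)
    stop("line variant (", line@variant, ") does not match model variant (",
         model@variant, ")")
  ratios <- line@expressionRatio
  model@reactions <- lapply(model@reactions, function(r) {
    if (is.na(r@gene)) return(r)
    if (!r@gene %in% names(ratios)) {
      if (r@gene %in% .endogenousGenes) return(r)  # unreported: ratio 1
      stop("expression ratio missing for gene-tagged reaction ", r@id,
           " (gene ", r@gene, ")")
    }
    r@law@V <- r@law@V * ratios[[r@gene]]
    r
  })
  model
}

#' Median line of a set of profiles
#'
#' Element-wise median of the expression ratios, hormone levels and
#' phenotypes over all profiles of one variant; used to construct the
#' type-level "median model". Medians of an even count are the arithmetic
#' mean of the two middle values. A hormone is flagged below detection in the
#' median line when more than half of the lines are below detection.
#'
#' @param profiles list of \linkS4class{LineProfile} objects, all of the same
#'   variant.
#' @param variant expected variant; defaults to the profiles' variant.
#' @return a \linkS4class{LineProfile} with lineId \code{"median_<variant>"}.
#' @export
medianLine <- function(profiles, variant = NULL) {
  if (!length(profiles)) stop("profile list must be non-empty")
  vars <- vapply(profiles, function(p) p@variant, "")
  if (is.null(variant)) variant <- vars[1]
  if (!all(vars == variant))
    stop("mixed variants in profile list: ", paste(unique(vars), collapse = ", "))
  genes <- unique(unlist(lapply(profiles, function(p) names(p@expressionRatio))))
  er <- vapply(genes, function(g) {
    stats::median(vapply(profiles, function(p) {
      if (g %in% names(p@expressionRatio)) p@expressionRatio[[g]] else NA_real_
    }, 0), na.rm = TRUE)
  }, 0)
  hs <- unique(unlist(lapply(profiles, function(p) p@hormones$hormone)))
  hlev <- vapply(hs, function(h) {
    stats::median(vapply(profiles, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i)) NA_real_ else p@hormones$level[i]
    }, 0), na.rm = TRUE)
  }, 0)
  hbd <- vapply(hs, function(h) {
    bd <- vapply(profiles, function(p) {
      i <- match(h, p@hormones$hormone)
      if (is.na(i)) NA else p@hormones$belowDetection[i]
    }, NA)
    mean(bd, na.rm = TRUE) > 0.5
  }, NA)
  ph <- vapply(.phenotypeNames, function(nm) {
    stats::median(vapply(profiles, function(p) p@phenotype[[nm]], 0), na.rm = TRUE)
  }, 0)
  new("LineProfile", lineId = paste0("median_", variant), variant = variant,
      expressionRatio = er,
      hormones = data.frame(hormone = hs, level = unname(hlev),
                            belowDetection = unname(hbd)),
      phenotype = ph)
}
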
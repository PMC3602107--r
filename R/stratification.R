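#' Classify sites by distance to the nearest TSS
#'
#' Sites within `proximalBp` (inclusive) of the nearest TSS are proximal;
#' sites beyond `distalBp` (strict) are distal; everything in between is
#' intermediate.  The absolute point-to-point distance is used for the
#' classification; the signed distance (positive downstream of the TSS in
#' the gene's reading direction) is kept alongside.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`
#' @param transcripts data.frame as from [readAnnotation()] (typically after
#'   [selectRepresentative()])
#' @param proximalBp proximal cutoff in bp (default 1000)
#' @param distalBp distal cutoff in bp (default 10000)
#' @return data.frame with columns `site_id`, `tss_distance` (signed),
#'   `distance_class` (`proximal`/`intermediate`/`distal`)
#' @export
classifyDistance <- function(sites, transcripts, proximalBp = 1000,
                             distalBp = 10000) {
  if (!nrow(transcripts)) stop("transcripts must be non-empty")
  asg <- orientSitesByNearestGene(sites, transcripts)
  d <- asg$distance
  cls <- ifelse(is.na(d), "distal",
         ifelse(d <= proximalBp, "proximal",
         ifelse(d > distalBp, "distal", "intermediate")))
  data.frame(site_id = sites$site_id, tss_distance = asg$signed_distance,
             distance_class = cls, stringsAsFactors = FALSE)
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param reads read count assigned to the transcript
#' @param exonBp summed exon length in bp (> 0)
#' @param mappedReads total mapped reads in the library (> 0)
#' @return RPKM value(s)
#' @export
rpkm <- function(reads, exonBp, mappedReads) {
  if (any(exonBp <= 0)) stop("exonBp must be positive")
  if (any(mappedReads <= 0)) stop("mappedReads must be positive")
  reads / (exonBp / 1000) / (mappedReads / 1e6)
}

#' Select one representative transcript per gene
#'
#' For alternatively spliced transcripts of the same gene, the transcript
#' with the highest expression is kept; ties go to the longest summed exon
#' length, then to the lexicographically smallest transcript id.
#'
#' @param transcripts data.frame as from [readAnnotation()], with
#'   `expression` present
#' @return data.frame with one row per gene
#' @export
selectRepresentative <- function(transcripts) {
  if (anyNA(transcripts$expression))
    stop("expression values required to select representative transcripts")
  o <- order(transcripts$gene_id, -transcripts$expression,
             -transcripts$exon_bp, transcripts$transcript_id)
  tx <- transcripts[o, , drop = FALSE]
  tx[!duplicated(tx$gene_id), , drop = FALSE]
}

#' Assign activator/repressor roles to sites
#'
#' Sites of TFs annotated as both activator and repressor are removed from
#' role analyses; sites of TFs absent from the table get role `"unknown"`
#' and are retained for analyses that do not stratify by role.
#'
#' @param sites data.frame with columns `site_id`, `tf`
#' @param roles data.frame as from [readRoles()]
#' @return data.frame with columns `site_id`, `tf`, `role` (`activator`,
#'   `repressor` or `unknown`); sites of dual-annotated TFs are absent
#' @export
assignRoles <- function(sites, roles) {
  if (anyDuplicated(roles$tf)) stop("TF appears more than once in role table")
  role <- roles$role[match(sites$tf, roles$tf)]
  role[is.na(role)] <- "unknown"
  keep <- role != "both"
  if (any(!keep))
    message(sum(!keep), " site(s) of dual-annotated TF(s) removed from role analyses")
  data.frame(site_id = sites$site_id[keep], tf = sites$tf[keep],
             role = role[keep], stringsAsFactors = FALSE)
}
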
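# Consequence-severity ranking and filtering of outlier SNPs.

# Ensembl VEP ordered consequence list (most to least severe) with impact
# classes. Embedded so runs are reproducible without network access; the
# version string is recorded in output headers.
.severity_version <- "ensembl-vep-110"

.severity_table <- function() {
  term <- c(
    "transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "transcript_amplification", "feature_elongation", "feature_truncation",
    "inframe_insertion", "inframe_deletion", "missense_variant",
    "protein_altering_variant", "splice_donor_5th_base_variant",
    "splice_region_variant", "splice_donor_region_variant",
    "splice_polypyrimidine_tract_variant",
    "incomplete_terminal_codon_variant", "start_retained_variant",
    "stop_retained_variant", "synonymous_variant", "coding_sequence_variant",
    "mature_miRNA_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant", "intron_variant",
    "NMD_transcript_variant", "non_coding_transcript_variant",
    "coding_transcript_variant", "upstream_gene_variant",
    "downstream_gene_variant", "TFBS_ablation", "TFBS_amplification",
    "TF_binding_site_variant", "regulatory_region_ablation",
    "regulatory_region_amplification", "regulatory_region_variant",
    "intergenic_variant", "sequence_variant"
  )
  impact <- c(
    rep("HIGH", 10), rep("MODERATE", 4), rep("LOW", 8), rep("MODIFIER", 19)
  )
  data.frame(rank = seq_along(term), term = term, impact = impact,
             stringsAsFactors = FALSE)
}

#' Embedded consequence-severity ranking
#'
#' The Ensembl ordered Sequence Ontology consequence list (most severe
#' first) with impact classes, embedded as package data so severity
#' ranking never depends on a network service.
#'
#' @return `data.frame` with columns `rank`, `term`, `impact`; the table
#'   version is in `attr(, "version")`.
#' @export
severity_table <- function() {
  out <- .severity_table()
  attr(out, "version") <- .severity_version
  out
}

.split_terms <- function(x) {
  unique(trimws(unlist(strsplit(x, "[,&]"))))
}

#' Most severe consequence of a variant
#'
#' @param terms Character vector of Sequence Ontology consequence terms,
#'   or a single comma/ampersand-separated string (both VEP dialects).
#' @return List with `term` (the most severe) and its `impact`.
#' @examples
#' most_severe(c("missense_variant", "stop_lost"))$term  # "stop_lost"
#' @export
most_severe <- function(terms) {
  if (length(terms) == 1L) terms <- .split_terms(terms)
  if (length(terms) == 0L || all(!nzchar(terms))) {
    stop("at least one consequence term is required")
  }
  tab <- .severity_table()
  ranks <- match(terms, tab$term)
  if (anyNA(ranks)) {
    stop("unknown consequence term(s): ",
         paste(terms[is.na(ranks)], collapse = ", "),
         " (severity table ", .severity_version, ")")
  }
  best <- which.min(ranks)
  list(term = terms[best], impact = tab$impact[ranks[best]])
}

#' Read a consequence annotation table
#'
#' Accepts VEP tab-separated output (columns `#Uploaded_variation` and
#' `Consequence`; multiple transcript rows per variant are merged) or a
#' minimal generic two-column TSV (`id`, comma-separated terms).
#'
#' @param path Path to the annotation TSV.
#' @return `data.frame` with columns `id` and `terms` (comma-separated).
#' @export
read_consequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^#Uploaded_variation", lines)
  if (length(hdr_idx)) {
    hdr <- strsplit(lines[hdr_idx[1]], "\t", fixed = TRUE)[[1]]
    body <- lines[-seq_len(hdr_idx[1])]
    body <- body[!startsWith(body, "##")]
    fields <- strsplit(body, "\t", fixed = TRUE)
    id_col <- which(hdr == "#Uploaded_variation")
    cq_col <- which(hdr == "Consequence")
    id <- vapply(fields, `[`, character(1), id_col)
    cq <- vapply(fields, `[`, character(1), cq_col)
  } else {
    body <- lines[!startsWith(lines, "#")]
    if (length(body) && grepl("^id\t", body[1])) body <- body[-1]
    fields <- strsplit(body, "\t", fixed = TRUE)
    id <- vapply(fields, `[`, character(1), 1L)
    cq <- vapply(fields, `[`, character(1), 2L)
  }
  merged <- tapply(cq, id, function(x) {
    paste(unique(unlist(lapply(x, .split_terms))), collapse = ",")
  })
  data.frame(id = names(merged), terms = unname(unlist(merged)),
             stringsAsFactors = FALSE)
}

#' Keep outliers whose most severe consequence is impactful
#'
#' Retains scan outliers whose most severe consequence is
#' `missense_variant` or any HIGH-impact term, preserving the scan's
#' decreasing delta-DAF order. Outliers without an annotation are reported
#' separately, not silently dropped.
#'
#' @param annotations Annotation table from [read_consequences()].
#' @param scan A `daf_scan_result` from [select_outliers()].
#' @return List with `kept` (`id`, `delta_daf`, `term`, `impact`) and
#'   `missing` (outlier ids lacking any annotation).
#' @export
filter_impactful <- function(annotations, scan) {
  stopifnot(inherits(scan, "daf_scan_result"))
  out <- scan$outliers
  idx <- match(out$id, annotations$id)
  missing <- out$id[is.na(idx)]
  kept <- list()
  for (k in which(!is.na(idx))) {
    ms <- most_severe(annotations$terms[idx[k]])
    if (ms$term == "missense_variant" || ms$impact == "HIGH") {
      kept[[length(kept) + 1L]] <- data.frame(
        id = out$id[k], delta_daf = out$delta_daf[k],
        term = ms$term, impact = ms$impact, stringsAsFactors = FALSE)
    }
  }
  kept <- if (length(kept)) do.call(rbind, kept) else
    data.frame(id = character(), delta_daf = numeric(),
               term = character(), impact = character(),
               stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  list(kept = kept, missing = missing)
}
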
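# End-to-end orchestration: contigs + domain-hit table -> element models,
# CDA types, captures and satellite arrays; aligned transposases ->
# distances, NJ tree, clade assignments.

#' Default detection thresholds for a scan
#'
#' All thresholds are echoed verbatim into the run report. Unknown keys in
#' overrides are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of thresholds.
#' @export
scan_config <- function(...) {
  defaults <- list(
    max_flank = 15000L,
    tir_motif = "CACTA", tir_min_len = 25L, tir_max_len = 40L,
    min_pair_identity = 0.70,
    end_window = 600L, unit_range = c(10L, 20L), min_copy_identity = 0.80,
    min_copies_per_end = 3L, tsd_len = 3L,
    hit_min_identity = 0.35, hit_min_similarity = 0.45,
    hit_min_aln_len = 0.8, hit_max_interruptions = 0L,
    hit_max_len_prop = 1.2,
    tnp2_target_len = 630L, tnp2_tolerance = 0.1,
    orf_min_len = 900L,
    sat_min_monomer = 30L, sat_max_monomer = 400L,
    sat_min_copies = 3.0, sat_min_copy_identity = 0.7)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, over)
}

#' Scan contigs for CACTA elements around filtered transposase anchors
#'
#' The pipeline order mirrors domain-anchored TE annotation: domain hits are
#' quality-filtered, full-length tnp2 (Transposase_21) hits become anchors,
#' terminal structure is searched around each anchor, coding intervals are
#' taken from the supplied GFF3 or from an ORF scan, domains are assigned to
#' ORFs and the CDA is typed, then captured fragments (non-canonical domain
#' hits outside coding sequence) and satellite arrays are annotated.
#'
#' @param contigs Path to a contigs FASTA, or a named character vector of
#'   sequences.
#' @param hits Path to a domain-hit table, or a data.frame in
#'   [load_domain_hits()] layout (half-open coordinates).
#' @param hits_dialect `"tsv"` or `"gff3"` (when `hits` is a path).
#' @param coding Optional path to a GFF3 of coding intervals (CDS features,
#'   contig coordinates); when absent, six-frame ORF scanning is used.
#' @param out_dir Optional output directory; when given, `elements.gff3`,
#'   `elements.tsv` and `report.json` are written there.
#' @param config From [scan_config()].
#' @return A run report (list): `config`, `n_anchors`, `elements` (list of
#'   element models), `table` (one summary row per element). Returned
#'   invisibly when `out_dir` is given.
#' @export
run_scan <- function(contigs, hits, hits_dialect = "tsv", coding = NULL,
                     out_dir = NULL, config = scan_config()) {
  seqs <- if (is.character(contigs) && length(contigs) == 1L &&
              file.exists(contigs)) read_fasta(contigs) else contigs
  hit_df <- if (is.character(hits)) load_domain_hits(hits, hits_dialect)
  else hits
  coding_gff <- if (!is.null(coding)) read_coding_gff3(coding)

  hit_df <- filter_hits(hit_df,
                        min_identity = config$hit_min_identity,
                        min_similarity = config$hit_min_similarity,
                        min_aln_len = config$hit_min_aln_len,
                        max_interruptions = config$hit_max_interruptions,
                        max_len_prop = config$hit_max_len_prop)
  anchors <- select_full_length_tnp2(hit_df, config$tnp2_target_len,
                                     config$tnp2_tolerance)
  elements <- list()
  for (k in seq_len(nrow(anchors))) {
    cid <- anchors$seqid[k]
    if (!cid %in% names(seqs)) next
    contig <- seqs[[cid]]
    el <- call_element(contig, interval(anchors$start[k], anchors$end[k]),
                       max_flank = config$max_flank,
                       config = config[c("tir_motif", "tir_min_len",
                                         "tir_max_len", "min_pair_identity",
                                         "end_window", "unit_range",
                                         "min_copy_identity",
                                         "min_copies_per_end", "tsd_len")],
                       contig_id = cid)
    el <- annotate_element_content(el, contig, hit_df, coding_gff, config)
    elements[[length(elements) + 1L]] <- el
  }
  report <- list(tool = "cactascan", version = as.character(
    utils::packageVersion("cactascan")),
    config = config, n_anchors = nrow(anchors),
    elements = elements, table = element_table(elements))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_elements_gff3(elements, file.path(out_dir, "elements.gff3"))
    utils::write.table(report$table, file.path(out_dir, "elements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' @noRd
annotate_element_content <- function(el, contig, hit_df, coding_gff, config) {
  span <- el$span
  eseq <- substr(contig, span$start, span$end - 1L)
  shift <- -(span$start - 1L)
  in_span <- hit_df$start >= span$start & hit_df$end <= span$end &
    hit_df$seqid == el$contig_id
  local_hits <- hit_df[in_span, , drop = FALSE]
  local_hits$start <- local_hits$start + shift
  local_hits$end <- local_hits$end + shift

  coding_ivs <- if (!is.null(coding_gff)) {
    sel <- coding_gff$seqid == el$contig_id &
      coding_gff$start >= span$start & coding_gff$end <= span$end
    lapply(which(sel), function(i)
      interval(coding_gff$start[i] + shift, coding_gff$end[i] + shift))
  } else {
    maximal_orfs(find_orfs(eseq, config$orf_min_len))
  }

  canon <- local_hits[local_hits$name %in% CANONICAL_DOMAINS, , drop = FALSE]
  # one hit per domain for classification: keep the highest identity
  if (nrow(canon)) {
    keep <- unlist(lapply(split(seq_len(nrow(canon)), canon$name),
                          function(ix) ix[which.max(canon$identity[ix])]))
    extra <- setdiff(seq_len(nrow(canon)), keep)
    canon_main <- canon[sort(keep), , drop = FALSE]
  } else canon_main <- canon
  el <- tryCatch(assign_orfs(el, coding_ivs, canon_main),
                 error = function(e) { el$coding_ivs <- coding_ivs; el })
  if (!is.null(el$domains))
    el$cda <- classify_cda(el$domains$name)
  # captured fragments: non-canonical hits outside coding sequence
  caps <- local_hits[startsWith(local_hits$name, "other:"), , drop = FALSE]
  if (nrow(caps) && !is.null(el$domains) && "TAD" %in% el$domains$name) {
    frag <- data.frame(label = sub("^other:", "", caps$name),
                       start = caps$start, end = caps$end)
    el$captures <- annotate_capture(el, frag)
  }
  if (nchar(eseq) >= config$sat_min_monomer * config$sat_min_copies) {
    arrays <- detect_tandem_array(eseq, config$sat_min_monomer,
                                  config$sat_max_monomer,
                                  config$sat_min_copies,
                                  config$sat_min_copy_identity)
    el$arrays <- lapply(arrays, function(a) {
      a$location <- locate_array_in_element(el, a)
      a
    })
  }
  el
}

#' @noRd
read_coding_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene", "mRNA", "exon")]
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr) + 1L,  # -> half-open
             stringsAsFactors = FALSE)
}

#' One summary row per element
#' @noRd
element_table <- function(elements) {
  if (length(elements) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer(),
                      completeness = character(), tir_length = integer(),
                      tir_identity = numeric(), subtir_motif = character(),
                      n_5prime = integer(), n_3prime = integer(),
                      tsd = character(), cda = character(),
                      n_captures = integer(), n_arrays = integer()))
  do.call(rbind, lapply(elements, function(el) data.frame(
    contig = el$contig_id,
    start = el$span$start, end = el$span$end,
    length = interval_length(el$span),
    completeness = el$completeness,
    tir_length = if (!is.null(el$tir)) el$tir$length else NA_integer_,
    tir_identity = if (!is.null(el$tir)) el$tir$pair_identity else NA_real_,
    subtir_motif = if (!is.null(el$subtir)) el$subtir$motif else NA_character_,
    n_5prime = if (!is.null(el$subtir)) el$subtir$n_5prime else 0L,
    n_3prime = if (!is.null(el$subtir)) el$subtir$n_3prime else 0L,
    tsd = if (!is.null(el$tsd)) el$tsd else NA_character_,
    cda = if (!is.null(el$cda)) el$cda$label else NA_character_,
    n_captures = if (!is.null(el$captures)) nrow(el$captures) else 0L,
    n_arrays = length(el$arrays))))
}

#' Write called elements as GFF3
#'
#' Features: `transposable_element` with nested `terminal_inverted_repeat`,
#' `repeat_region` (subTIR units) and `satellite_DNA`, linked by ID/Parent.
#'
#' @param elements List of element models.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(elements, path) {
  feats <- list()
  add <- function(seqid, type, start, end, strand, attrs) {
    feats[[length(feats) + 1L]] <<- data.frame(
      seqid = seqid, source = "cactascan", type = type,
      start = start, end = end, score = ".", strand = strand,
      phase = ".", attributes = attrs)
  }
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    eid <- sprintf("%s_element%02d", el$contig_id, i)
    add(el$contig_id, "transposable_element", el$span$start, el$span$end, "+",
        paste0("ID=", eid, ";completeness=", el$completeness,
               if (!is.null(el$cda)) paste0(";cda=", el$cda$label) else "",
               if (!is.null(el$tsd)) paste0(";tsd=", el$tsd) else ""))
    if (!is.null(el$tir)) {
      add(el$contig_id, "terminal_inverted_repeat",
          el$tir$left_iv$start, el$tir$left_iv$end, "+",
          paste0("Parent=", eid, ";side=left"))
      add(el$contig_id, "terminal_inverted_repeat",
          el$tir$right_iv$start, el$tir$right_iv$end, "-",
          paste0("Parent=", eid, ";side=right"))
    }
    if (!is.null(el$subtir) && nrow(el$subtir$copies)) {
      cp <- el$subtir$copies
      for (j in seq_len(nrow(cp)))
        add(el$contig_id, "repeat_region", cp$start[j], cp$end[j],
            cp$strand[j], paste0("Parent=", eid, ";class=subTIR_unit",
                                 ";identity=", sprintf("%.3f", cp$identity[j])))
    }
    for (a in el$arrays) {
      off <- el$span$start - 1L
      add(el$contig_id, "satellite_DNA", a$iv$start + off, a$iv$end + off, "+",
          paste0("Parent=", eid, ";monomer_len=", a$monomer_len,
                 ";copy_number=", a$copy_number))
    }
  }
  write_gff3(if (length(feats)) do.call(rbind, feats) else
    data.frame(seqid = character(), source = character(), type = character(),
               start = integer(), end = integer(), score = character(),
               strand = character(), phase = character(),
               attributes = character()), path)
}

#' @noRd
report_json <- function(report) {
  list(tool = report$tool, version = report$version,
       config = report$config, n_anchors = report$n_anchors,
       n_elements = length(report$elements),
       elements = report$table)
}

#' Comparative transposase analysis over an alignment
#'
#' Computes the pairwise distance matrix under the chosen model, a
#' neighbor-joining tree, and (given labeled references) nearest-reference
#' clade assignments for the remaining sequences.
#'
#' @param alignment Path to an aligned FASTA, or a named character vector.
#' @param model `"t92"` (DNA) or `"p_protein"`.
#' @param gamma_shape Optional gamma shape for `t92`.
#' @param references Optional data.frame with columns `label`, `clade`;
#'   `label` must name sequences in the alignment.
#' @param cutoff Clade-assignment distance cutoff.
#' @param out_dir Optional output directory; writes `distances.tsv`,
#'   `distances.phylip`, `tree.nwk`, `assignments.tsv`, `report.json`.
#' @return List with `distances`, `tree` (Newick), `assignments`
#'   (data.frame or NULL). Invisible when `out_dir` is given.
#' @export
run_compare <- function(alignment, model = c("t92", "p_protein"),
                        gamma_shape = NULL, references = NULL, cutoff = 0.5,
                        out_dir = NULL) {
  model <- match.arg(model)
  seqs <- if (is.character(alignment) && length(alignment) == 1L &&
              file.exists(alignment)) read_aligned_fasta(alignment)
  else alignment
  d <- distance_matrix(seqs, model, gamma_shape)
  tree <- nj_tree(d)
  assignments <- NULL
  if (!is.null(references)) {
    miss <- setdiff(references$label, names(seqs))
    if (length(miss)) stop("reference(s) not in alignment: ",
                           paste(miss, collapse = ", "))
    refs <- data.frame(label = references$label, clade = references$clade,
                       seq = unname(seqs[references$label]))
    queries <- setdiff(names(seqs), references$label)
    assignments <- do.call(rbind, lapply(queries, function(q) {
      as.data.frame(assign_clade(seqs[q], refs, model, cutoff))
    }))
  }
  out <- list(model = model, distances = d, tree = tree,
              assignments = assignments)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(unclass(d)),
                       file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE)
    write_phylip(d, file.path(out_dir, "distances.phylip"))
    writeLines(tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(assignments))
      utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(model = model, n_sequences = length(seqs),
                              tree = tree),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

#' Read an aligned FASTA (gaps allowed) as uppercase strings
#' @noRd
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment: ", path)
  stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}
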
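# Codon-aware protein consequences and HGVS-style c./p. nomenclature for
# single SNVs and jointly applied MNV edits, plus the naive-vs-merged
# discordance classification that flags diagnostic risk.

EFFECT_CLASSES <- c("synonymous", "stop_retained", "missense", "stop_gained",
                    "stop_lost", "start_lost")

#' Default severity ranks for consequence classes
#'
#' Synonymous-like outcomes rank 1, missense 2, and loss-of-function-like
#' outcomes (premature stop, stop loss, start loss) 4 — the ranking used to
#' call a merged annotation more or less severe than the naive per-SNV
#' annotations under a dominant, loss-of-function testing model. Supplied as
#' configuration so laboratories can re-rank.
#'
#' @export
DEFAULT_SEVERITY <- c(synonymous = 1, stop_retained = 1, missense = 2,
                      start_lost = 4, stop_lost = 4, stop_gained = 4)

#' Annotate one or more joint single-base CDS edits
#'
#' Applies all edits jointly to the coding sequence of `tx`, retranslates
#' the affected codon(s), and derives effect class plus HGVS-style `c.` and
#' `p.` strings. A single affected codon follows simple substitution
#' semantics; when the stop codon is lost, the distance to the next in-frame
#' stop in the transcript's downstream sequence is reported as the
#' `ext*N` extension length. Coordinates are 1-based inclusive.
#'
#' Edits may be given in coding space (columns `c_position`, `alt`, with
#' `alt` on the coding strand) or genomic space (columns `pos`, `alt`, with
#' `alt` on the genomic plus strand; complemented internally for
#' minus-strand transcripts).
#'
#' @param tx An `mnv_transcript`.
#' @param reference A `DNAStringSet`.
#' @param edits data.frame of single-base substitutions (see above); must be
#'   mutually non-overlapping, inside the CDS, and differ from the
#'   reference base.
#' @return Object of class `mnv_consequence` with fields `effect_class`,
#'   `codon_numbers`, `ref_codons`, `alt_codons`, `ref_aa`, `alt_aa`,
#'   `per_codon_effect`, `hgvs_c`, `hgvs_p`, `extension_length`, `edits`.
#' @export
annotate_variant <- function(tx, reference, edits) {
  edits <- as.data.frame(edits)
  if (nrow(edits) == 0) stop("no edits supplied")
  if (!"c_position" %in% names(edits)) {
    if (!all(c("pos", "alt") %in% names(edits)))
      stop("edits need columns c_position+alt or pos+alt")
    cc <- genomic_to_cds(tx, edits$pos)   # errors if outside CDS
    alt <- toupper(edits$alt)
    if (tx$strand == "-") alt <- vapply(alt, revcomp, character(1))
    edits <- data.frame(c_position = cc$c_position, alt = alt)
  }
  edits$c_position <- as.integer(edits$c_position)
  edits$alt <- toupper(edits$alt)
  if (any(edits$c_position < 1 | edits$c_position > tx$cds_length))
    stop("edit position outside CDS [1, ", tx$cds_length, "] of ",
         tx$transcript_id)
  if (anyDuplicated(edits$c_position))
    stop("edits must be mutually non-overlapping")
  if (any(!edits$alt %in% c("A", "C", "G", "T")))
    stop("edit alt bases must be single A/C/G/T")
  edits <- edits[order(edits$c_position), , drop = FALSE]

  cds <- coding_sequence(tx, reference)
  edits$ref <- vapply(edits$c_position, function(p) substr(cds, p, p),
                      character(1))
  if (any(edits$ref == edits$alt))
    stop("edit at c.", edits$c_position[edits$ref == edits$alt][1],
         " equals the reference base (not a variant)")
  alt_cds <- cds
  for (i in seq_len(nrow(edits)))
    substr(alt_cds, edits$c_position[i], edits$c_position[i]) <- edits$alt[i]

  codons <- sort(unique(cds_to_codon(edits$c_position)$codon_number))
  codon_str <- function(s, k) substr(s, (k - 1L) * 3L + 1L, (k - 1L) * 3L + 3L)
  ref_codons <- vapply(codons, function(k) codon_str(cds, k), character(1))
  alt_codons <- vapply(codons, function(k) codon_str(alt_cds, k), character(1))
  ref_aa <- vapply(ref_codons, translate_codon, character(1), USE.NAMES = FALSE)
  alt_aa <- vapply(alt_codons, translate_codon, character(1), USE.NAMES = FALSE)

  per_effect <- character(length(codons))
  ext <- NA_integer_
  ext_known <- TRUE
  for (i in seq_along(codons)) {
    per_effect[i] <-
      if (ref_aa[i] == "*" && alt_aa[i] == "*") "stop_retained"
      else if (ref_aa[i] == "*") "stop_lost"
      else if (alt_aa[i] == "*") "stop_gained"
      else if (codons[i] == 1L && ref_aa[i] == "Met" && alt_aa[i] != "Met")
        "start_lost"
      else if (ref_aa[i] == alt_aa[i]) "synonymous"
      else "missense"
    if (per_effect[i] == "stop_lost") {
      ext <- stop_extension_length(tx$downstream_seq)
      if (is.na(ext)) ext_known <- FALSE
    }
  }
  effect <- per_effect[which.max(DEFAULT_SEVERITY[per_effect])]

  obj <- structure(
    list(effect_class = effect, codon_numbers = codons,
         ref_codons = ref_codons, alt_codons = alt_codons,
         ref_aa = ref_aa, alt_aa = alt_aa, per_codon_effect = per_effect,
         hgvs_c = NA_character_, hgvs_p = NA_character_,
         extension_length = ext, extension_known = ext_known,
         edits = edits[, c("c_position", "ref", "alt")],
         transcript_id = tx$transcript_id, gene = tx$gene),
    class = "mnv_consequence")
  hg <- hgvs_strings(obj, alt_cds = alt_cds)
  obj$hgvs_c <- hg[["hgvs_c"]]
  obj$hgvs_p <- hg[["hgvs_p"]]
  obj
}

#' @export
print.mnv_consequence <- function(x, ...) {
  cat(sprintf("<consequence %s: %s %s [%s]>\n", x$transcript_id, x$hgvs_c,
              x$hgvs_p, x$effect_class))
  invisible(x)
}

#' Stop-loss extension length
#'
#' After a variant abolishes the stop codon, translation continues into the
#' downstream (post-stop) sequence. Returns `N`, the 1-based index — in
#' codons, starting immediately after the original stop position — of the
#' first in-frame stop codon, i.e. the numeral in HGVS `ext*N`. Returns
#' `NA` when no in-frame stop exists within the available sequence (the
#' `p.` string then uses `ext*?` rather than failing).
#'
#' @param downstream DNA string beyond the original stop codon, in coding
#'   orientation.
#' @return Integer codon count, or `NA_integer_`.
#' @export
stop_extension_length <- function(downstream) {
  if (is.null(downstream) || is.na(downstream) || nchar(downstream) < 3)
    return(NA_integer_)
  n_codons <- nchar(downstream) %/% 3L
  for (k in seq_len(n_codons)) {
    codon <- substr(downstream, (k - 1L) * 3L + 1L, (k - 1L) * 3L + 3L)
    if (grepl("[^ACGT]", codon)) return(NA_integer_)
    if (translate_codon(codon) == "*") return(k)
  }
  NA_integer_
}

# p. descriptor for one affected codon (without the "p." prefix)
p_descriptor <- function(codon_number, ref_aa, alt_aa, effect,
                         extension_length, extension_known) {
  switch(effect,
    synonymous = paste0(ref_aa, codon_number, ref_aa),
    missense = paste0(ref_aa, codon_number, alt_aa),
    stop_gained = paste0(ref_aa, codon_number, "*"),
    stop_retained = paste0("*", codon_number, "*"),
    stop_lost = paste0("*", codon_number, alt_aa, "ext*",
                       if (extension_known && !is.na(extension_length))
                         extension_length else "?"),
    start_lost = paste0(ref_aa, codon_number, "?"))
}

#' Regenerate HGVS c. and p. strings from consequence fields
#'
#' Single-SNV edits give `c.POSref>alt`; multi-base edits give
#' `c.START_ENDdelins<ALT>` where the span runs from the first to the last
#' edited base and includes unchanged intervening bases. Protein strings
#' follow the paper-facing style: missense `p.RefPosAlt`, synonymous
#' `p.RefPosRef`, stop gained `p.RefPos*`, stop retained `p.*Pos*`,
#' stop lost `p.*PosAAext*N`, start lost `p.RefPos?`; multi-codon edits
#' give a compound `p.[..;..]`.
#'
#' @param consequence An `mnv_consequence`.
#' @param alt_cds Optional edited coding sequence (recomputed span alt when
#'   absent).
#' @return Named character vector with elements `hgvs_c` and `hgvs_p`.
#' @export
hgvs_strings <- function(consequence, alt_cds = NULL) {
  ed <- consequence$edits
  if (nrow(ed) == 1) {
    hgvs_c <- sprintf("c.%d%s>%s", ed$c_position, ed$ref, ed$alt)
  } else {
    lo <- min(ed$c_position); hi <- max(ed$c_position)
    if (!is.null(alt_cds)) {
      alt_span <- substr(alt_cds, lo, hi)
    } else {
      # rebuild the span from the affected codons
      first_c <- (min(consequence$codon_numbers) - 1L) * 3L
      span <- paste(consequence$alt_codons, collapse = "")
      alt_span <- substr(span, lo - first_c, hi - first_c)
    }
    hgvs_c <- sprintf("c.%d_%ddelins%s", lo, hi, alt_span)
  }
  descs <- vapply(seq_along(consequence$codon_numbers), function(i)
    p_descriptor(consequence$codon_numbers[i], consequence$ref_aa[i],
                 consequence$alt_aa[i], consequence$per_codon_effect[i],
                 consequence$extension_length, consequence$extension_known),
    character(1))
  hgvs_p <- if (length(descs) == 1) paste0("p.", descs)
    else paste0("p.[", paste(descs, collapse = ";"), "]")
  c(hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

#' Severity of a consequence
#'
#' @param consequence An `mnv_consequence`.
#' @param severity Named rank vector (default [DEFAULT_SEVERITY]).
#' @return Integer severity (maximum over affected codons).
#' @export
consequence_severity <- function(consequence, severity = DEFAULT_SEVERITY) {
  max(severity[consequence$per_codon_effect])
}

#' Classify naive-vs-merged annotation discordance
#'
#' Compares the per-SNV (naive) consequences of a cluster's members with the
#' consequence of the jointly applied MNV. The merged annotation being more
#' severe than every naive annotation is a false-negative risk (the naive
#' pipeline would under-call); less severe, a false-positive risk. Equal
#' severity with a different residue outcome is `changed_effect`;
#' `concordant` requires every merged per-codon outcome to be reproduced by
#' a naive annotation at that codon.
#'
#' @param naive List of `mnv_consequence` (one per member SNV); non-empty.
#' @param merged The merged `mnv_consequence`.
#' @param severity Named rank vector (default [DEFAULT_SEVERITY]).
#' @return Object of class `discordance_record` with fields `naive`,
#'   `merged`, `category`, `severity_naive_max`, `severity_merged`.
#' @export
classify_discordance <- function(naive, merged,
                                 severity = DEFAULT_SEVERITY) {
  stopifnot(length(naive) >= 1)
  sev_n <- max(vapply(naive, consequence_severity, numeric(1),
                      severity = severity))
  sev_m <- consequence_severity(merged, severity = severity)
  outcome_keys <- function(x) paste0(x$codon_numbers, ":", x$alt_aa, ":",
                                     x$per_codon_effect)
  naive_keys <- unlist(lapply(naive, outcome_keys))
  category <-
    if (sev_m > sev_n) "false_negative_risk"
    else if (sev_m < sev_n) "false_positive_risk"
    else if (all(outcome_keys(merged) %in% naive_keys)) "concordant"
    else "changed_effect"
  structure(list(naive = naive, merged = merged, category = category,
                 severity_naive_max = sev_n, severity_merged = sev_m),
            class = "discordance_record")
}

#' @export
print.discordance_record <- function(x, ...) {
  cat(sprintf("<discordance %s: naive {%s} vs merged %s>\n", x$category,
              paste(vapply(x$naive, function(n) n$hgvs_p, character(1)),
                    collapse = ", "), x$merged$hgvs_p))
  invisible(x)
}
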
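## Consensus-interface contact classification and energy tables ---------------

CONSENSUS_LABELS <- c("conserved", "variable1", "variable2", "other")

#' Consensus interface template
#'
#' An ordered set of template positions of a GAP-domain interface, each with
#' a region label and the set of partner (substrate) residue numbers
#' contacted at that position in reference complexes. Templates are user
#' input (e.g. digitized from published interface grids), not computed here.
#'
#' @param position integer or character template position ids (unique).
#' @param label region label per position: `"conserved"`, `"variable1"`,
#'   `"variable2"` or `"other"`.
#' @param partner_residues list (one element per position) of integer
#'   substrate residue numbers contacted at that position.
#' @return Object of class `"consensus_template"`.
#' @export
consensus_template <- function(position, label, partner_residues) {
  stopifnot(length(position) == length(label),
            length(position) == length(partner_residues))
  if (anyDuplicated(position))
    stop("template position ids must be unique", call. = FALSE)
  bad <- setdiff(unique(label), CONSENSUS_LABELS)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(CONSENSUS_LABELS, collapse = "/"), call. = FALSE)
  structure(list(position = as.character(position), label = label,
                 partner_residues = lapply(partner_residues, as.integer)),
            class = "consensus_template")
}

#' Read a consensus template from TSV
#'
#' Columns: `position`, `label`, `partner_residues` (comma-separated
#' integers; may be empty).
#'
#' @param file path to a tab-separated file.
#' @return A [consensus_template()].
#' @export
read_consensus_template <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  consensus_template(df$position, df$label,
                     lapply(strsplit(df$partner_residues, ","),
                            function(v) as.integer(v[nzchar(trimws(v))])))
}

#' Residue-to-template alignment map
#'
#' Maps query residues (chain, resseq) to template position ids, as produced
#' by a sequence alignment. The map must be injective in both directions;
#' unmapped residues are simply absent.
#'
#' @param chain,resseq query residue identity vectors.
#' @param position template position id per residue.
#' @return Object of class `"alignment_map"`.
#' @export
alignment_map <- function(chain, resseq, position) {
  stopifnot(length(chain) == length(resseq), length(chain) == length(position))
  rk <- paste0(chain, ":", resseq)
  if (anyDuplicated(rk))
    stop("alignment map is not injective: duplicate residues ",
         paste(unique(rk[duplicated(rk)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(position))
    stop("alignment map is not injective: duplicate positions ",
         paste(unique(position[duplicated(position)]), collapse = ", "),
         call. = FALSE)
  structure(list(chain = chain, resseq = as.integer(resseq),
                 position = as.character(position)), class = "alignment_map")
}

#' Read an alignment map from TSV
#'
#' Columns: `chain`, `resseq`, `position`.
#'
#' @param file path to a tab-separated file.
#' @return An [alignment_map()].
#' @export
read_alignment_map <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  alignment_map(as.character(df$chain), df$resseq, df$position)
}

#' Classify observed contacts against a consensus template
#'
#' Each persistence record pairs a GAP-side residue (`chain_a`, `resseq_a`)
#' with a substrate residue (`resseq_b`). A record is `matched` when its
#' GAP residue maps to a template position whose partner set contains the
#' substrate residue, `unmatched` when the residue maps but the partner
#' differs, and `unmapped` when the residue has no template position. The
#' three classes partition the records.
#'
#' @param records a [persistence()] data frame (or any data frame with
#'   `chain_a`, `resseq_a`, `resseq_b`, optionally `tier`).
#' @param amap an [alignment_map()] for the GAP chain.
#' @param template a [consensus_template()].
#' @return `records` with `template_position` and `match_class` columns
#'   added; a per-tier count table is attached as attribute `"tier_counts"`
#'   when tiers are present.
#' @export
classify_contacts <- function(records, amap, template) {
  rk <- paste0(amap$chain, ":", amap$resseq)
  qk <- paste0(records$chain_a, ":", records$resseq_a)
  pos <- amap$position[match(qk, rk)]
  tmpl_idx <- match(pos, template$position)
  cls <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (is.na(pos[i]) || is.na(tmpl_idx[i])) {
      cls[i] <- "unmapped"
    } else if (records$resseq_b[i] %in% template$partner_residues[[tmpl_idx[i]]]) {
      cls[i] <- "matched"
    } else {
      cls[i] <- "unmatched"
    }
  }
  records$template_position <- pos
  records$match_class <- factor(cls, levels = c("matched", "unmatched", "unmapped"))
  if (!is.null(records$tier))
    attr(records, "tier_counts") <- table(tier = records$tier,
                                          class = records$match_class)
  records
}

#' Binding-energy ratio between two complexes
#'
#' Ratio of two binding free energies as a percentage,
#' `100 * dG[numerator] / dG[denominator]`, rounded to one decimal. With both
#' values negative (the usual case for binding free energies) the signs
#' cancel and the result is the ratio of magnitudes; mixed signs trigger a
#' warning since the percentage is then not a magnitude comparison.
#'
#' @param table named numeric vector of binding free energies (kcal/mol), or
#'   a data frame with `label` and `dG` columns.
#' @param numerator,denominator labels to compare.
#' @return Percentage, rounded to one decimal.
#' @export
energy_ratio <- function(table, numerator, denominator) {
  if (is.data.frame(table)) {
    dg <- stats::setNames(table$dG, table$label)
  } else dg <- table
  miss <- setdiff(c(numerator, denominator), names(dg))
  if (length(miss))
    stop("label(s) not in energy table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- dg[[numerator]]; den <- dg[[denominator]]
  if (!is.finite(num) || !is.finite(den) || den == 0)
    stop("energies must be finite with nonzero denominator", call. = FALSE)
  if (sign(num) != sign(den))
    warning("energies have mixed signs; the percentage is not a ratio of magnitudes",
            call. = FALSE)
  round(100 * num / den, 1)
}

#' Read a binding-energy table from TSV
#'
#' Columns: `label`, `dG` (kcal/mol). Unicode minus signs as they appear in
#' typeset tables are normalized to ASCII.
#'
#' @param file path to a tab-separated file.
#' @return Named numeric vector of energies.
#' @export
read_energy_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  dg <- as.numeric(gsub("[−‒–]", "-", trimws(df$dG)))
  if (anyNA(dg)) stop("non-numeric dG entries in ", file, call. = FALSE)
  stats::setNames(dg, df$label)
}

#' Persistence tier edge in nanoseconds
#'
#' Converts a tier edge expressed as a fraction of the trajectory into
#' nanoseconds: `total_ns * fraction`. Over a 2 microsecond trajectory the
#' 5%, 1% and 0.1% edges are 100, 20 and 2 ns.
#'
#' @param total_ns trajectory length, ns (> 0).
#' @param fraction tier edge as a fraction in (0, 1).
#' @return Threshold in ns.
#' @export
tier_threshold_ns <- function(total_ns, fraction) {
  stopifnot(total_ns > 0, fraction > 0, fraction < 1)
  total_ns * fraction
}
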
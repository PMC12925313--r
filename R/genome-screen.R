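#' Read a CheckM-style genome quality table
#'
#' Parses a tab-separated quality table with at least the columns
#' \code{Bin Id}, \code{Completeness} and \code{Contamination} (extra columns
#' are ignored; column matching is case-insensitive and tolerant of spaces vs
#' underscores).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns \code{genome_id}, \code{completeness}
#'   and \code{contamination}.
#' @export
read_checkm <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  norm <- tolower(gsub("[ _]+", "", names(df)))
  pick <- function(key) {
    i <- match(key, norm)
    if (is.na(i)) stop("CheckM table is missing a '", key, "' column: ", path)
    df[[i]]
  }
  data.frame(
    genome_id     = as.character(pick("binid")),
    completeness  = as.numeric(pick("completeness")),
    contamination = as.numeric(pick("contamination")),
    stringsAsFactors = FALSE
  )
}

#' Filter genomes on completeness and contamination
#'
#' A genome is retained only when its estimated completeness is at least
#' \code{min_completeness} percent and its contamination is at most
#' \code{max_contamination} percent; violating either bound removes it.
#'
#' @param records Data frame with columns \code{genome_id},
#'   \code{completeness} (percent, 0-100) and \code{contamination}
#'   (percent, >= 0), e.g. from [read_checkm()].
#' @param min_completeness Minimum completeness in percent. Default 90.
#' @param max_contamination Maximum contamination in percent. Default 5.
#' @return Character vector of retained genome ids, in input order.
#' @export
filter_genomes <- function(records, min_completeness = 90, max_contamination = 5) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (min_completeness < 0 || min_completeness > 100)
    stop("min_completeness must lie in [0, 100]")
  if (max_contamination < 0) stop("max_contamination must be >= 0")
  bad <- records$completeness < 0 | records$completeness > 100 |
    records$contamination < 0 | is.na(records$completeness) |
    is.na(records$contamination)
  if (any(bad)) {
    stop("invalid quality record for genome(s): ",
         paste(records$genome_id[bad], collapse = ", "))
  }
  keep <- records$completeness >= min_completeness &
    records$contamination <= max_contamination
  records$genome_id[keep]
}

# Column layout of HMMER 3.x per-domain tabular output (hmmsearch --domtblout).
# The target is the ORF, the query is the profile; description (col >= 23) may
# contain spaces and is ignored.
.domtbl_cols <- c(
  target_name = 1L, target_acc = 2L, tlen = 3L, query_name = 4L,
  query_acc = 5L, qlen = 6L, full_evalue = 7L, full_score = 8L,
  full_bias = 9L, dom_n = 10L, dom_of = 11L, c_evalue = 12L, i_evalue = 13L,
  dom_score = 14L, dom_bias = 15L, hmm_from = 16L, hmm_to = 17L,
  ali_from = 18L, ali_to = 19L, env_from = 20L, env_to = 21L, acc = 22L
)

#' Parse HMMER per-domain tabular output (domtblout)
#'
#' Reads the whitespace-delimited per-domain table written by
#' \code{hmmsearch --domtblout}. One row is returned per domain line; comment
#' lines (starting with \code{#}) are skipped. The profile (query) is treated
#' as the gene family, the target as the ORF.
#'
#' @param path Path to a domtblout file for one genome.
#' @param genome_id Genome identifier to attach to every hit. Defaults to the
#'   file name without extension.
#' @return A hit table: data frame with columns \code{genome_id},
#'   \code{family_id}, \code{orf_id}, \code{bitscore} (full-sequence score),
#'   \code{evalue} (full-sequence E-value), \code{hmm_from}, \code{hmm_to}
#'   (1-based inclusive profile coordinates of the domain alignment) and
#'   \code{profile_length}.
#' @export
parse_domtbl <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) return(empty_hit_table())
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[i]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 22) {
      stop("malformed domtblout line ", ln, " in ", path,
           ": expected >= 22 columns, found ", length(fields))
    }
    out[[i]] <- stats::setNames(fields[.domtbl_cols], names(.domtbl_cols))
  }
  m <- do.call(rbind, out)
  hits <- data.frame(
    genome_id      = genome_id,
    family_id      = m[, "query_name"],
    orf_id         = m[, "target_name"],
    bitscore       = as.numeric(m[, "full_score"]),
    evalue         = as.numeric(m[, "full_evalue"]),
    hmm_from       = as.integer(m[, "hmm_from"]),
    hmm_to         = as.integer(m[, "hmm_to"]),
    profile_length = as.integer(m[, "qlen"]),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(hits$bitscore) | is.na(hits$evalue) |
                 is.na(hits$hmm_from) | is.na(hits$hmm_to) |
                 is.na(hits$profile_length))
  if (length(bad)) {
    stop("malformed domtblout line ", rows[bad[1]], " in ", path,
         ": non-numeric score/coordinate fields")
  }
  hits
}

#' @rdname parse_domtbl
#' @param dir Directory containing one domtblout file per genome
#'   (\code{<genome_id>.<ext>}).
#' @param pattern File name pattern passed to [list.files()].
#' @export
parse_domtbl_dir <- function(dir, pattern = "\\.(tsv|txt|domtbl|domtblout)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no domtblout files found in ", dir)
  do.call(rbind, lapply(files, parse_domtbl))
}

empty_hit_table <- function() {
  data.frame(genome_id = character(), family_id = character(),
             orf_id = character(), bitscore = numeric(), evalue = numeric(),
             hmm_from = integer(), hmm_to = integer(),
             profile_length = integer(), stringsAsFactors = FALSE)
}

#' Read a profile metadata table
#'
#' TSV with columns \code{family_id}, \code{threshold} (KEGG-recommended
#' bitscore reporting threshold, or NA when KEGG specifies none) and
#' \code{n_known_sequences} (number of sequences known for the family in the
#' source database).
#'
#' @param path Path to the TSV file.
#' @return Data frame with those three columns.
#' @export
read_profile_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("family_id", "threshold", "n_known_sequences")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("profile table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$family_id <- as.character(df$family_id)
  df$threshold <- suppressWarnings(as.numeric(df$threshold))
  df$n_known_sequences <- as.integer(df$n_known_sequences)
  df[need]
}

#' Drop families backed by too few known sequences
#'
#' Profiles built from small families are poorly supported and prone to false
#' positives; families with fewer than \code{min_seqs} known sequences are
#' excluded (strictly fewer: a family with exactly \code{min_seqs} is kept).
#'
#' @param profiles Profile metadata, as from [read_profile_meta()].
#' @param min_seqs Minimum number of known sequences. Default 200.
#' @return The filtered profile table.
#' @export
exclude_small_families <- function(profiles, min_seqs = 200) {
  stopifnot(min_seqs >= 0)
  profiles[profiles$n_known_sequences >= min_seqs, , drop = FALSE]
}

# Collapse per-domain rows to one row per (genome, family, ORF): coverage from
# the union of profile spans, score/evalue from the full-sequence values.
aggregate_domains <- function(hits) {
  if (nrow(hits) == 0) {
    out <- empty_hit_table()
    out$cover <- numeric()
    return(out)
  }
  key <- paste(hits$genome_id, hits$family_id, hits$orf_id, sep = "\r")
  idx <- split(seq_len(nrow(hits)), key)
  rows <- lapply(idx, function(i) {
    h <- hits[i, , drop = FALSE]
    covered <- union_span_length(h$hmm_from, h$hmm_to)
    best <- which.max(h$bitscore)
    data.frame(
      genome_id = h$genome_id[1], family_id = h$family_id[1],
      orf_id = h$orf_id[1],
      bitscore = h$bitscore[best], evalue = h$evalue[best],
      hmm_from = min(h$hmm_from), hmm_to = max(h$hmm_to),
      profile_length = h$profile_length[1],
      cover = covered / h$profile_length[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Total length covered by a union of 1-based inclusive intervals.
union_span_length <- function(from, to) {
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  total <- 0L; cur_from <- from[1]; cur_to <- to[1]
  for (i in seq_along(from)[-1]) {
    if (from[i] <= cur_to + 1L) {
      cur_to <- max(cur_to, to[i])
    } else {
      total <- total + (cur_to - cur_from + 1L)
      cur_from <- from[i]; cur_to <- to[i]
    }
  }
  total + (cur_to - cur_from + 1L)
}

#' Apply homology-evidence reporting thresholds
#'
#' A hit is kept when the family has a database-recommended bitscore
#' threshold and the full-sequence bitscore reaches it; for families without
#' a recommended threshold, the hit must satisfy both the E-value cutoff and
#' the query-cover threshold. Query cover is the fraction of the HMM profile
#' length spanned by the domain alignments (union of profile spans across
#' domains of the same ORF).
#'
#' @param hits Hit table from [parse_domtbl()] / [parse_domtbl_dir()].
#' @param profiles Profile metadata (see [read_profile_meta()]); every family
#'   appearing in \code{hits} must be listed.
#' @param fallback_evalue E-value cutoff for families without a recommended
#'   threshold. Default 1e-20.
#' @param min_query_cover Minimum profile coverage fraction for families
#'   without a recommended threshold. Default 0.75.
#' @return The surviving hits, one row per (genome, family, ORF), with a
#'   \code{cover} column added.
#' @export
apply_thresholds <- function(hits, profiles, fallback_evalue = 1e-20,
                             min_query_cover = 0.75) {
  agg <- aggregate_domains(hits)
  if (nrow(agg) == 0) return(agg)
  unknown <- setdiff(unique(agg$family_id), profiles$family_id)
  if (length(unknown)) {
    stop("hit(s) reference unknown family id(s): ",
         paste(unknown, collapse = ", "))
  }
  thr <- profiles$threshold[match(agg$family_id, profiles$family_id)]
  keep <- ifelse(!is.na(thr),
                 agg$bitscore >= thr,
                 agg$evalue <= fallback_evalue & agg$cover >= min_query_cover)
  out <- agg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the best hit per genome and family
#'
#' When a family matches several ORFs of one genome, only the
#' highest-bitscore hit is retained. Bitscore ties are broken by the lower
#' E-value, then by lexicographic ORF id, so the result is deterministic.
#'
#' @param hits A hit table.
#' @return Hit table with at most one row per (genome, family) pair.
#' @export
best_hit_per_family <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$genome_id, hits$family_id, -hits$bitscore, hits$evalue,
             hits$orf_id)
  h <- hits[o, , drop = FALSE]
  key <- paste(h$genome_id, h$family_id, sep = "\r")
  out <- h[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a binary gene-family presence matrix
#'
#' @param hits Surviving hit table.
#' @param genomes Character vector of genome ids (matrix rows, in order).
#' @param families Character vector of family ids (matrix columns, in order).
#' @return Integer matrix of 0/1 with genomes as rows and families as
#'   columns; a cell is 1 iff at least one hit exists for the pair. Hits for
#'   genomes or families outside the requested sets are ignored.
#' @export
build_presence_matrix <- function(hits, genomes, families) {
  stopifnot(length(genomes) > 0, length(families) > 0)
  if (anyDuplicated(genomes)) stop("duplicate genome ids")
  if (anyDuplicated(families)) stop("duplicate family ids")
  m <- matrix(0L, nrow = length(genomes), ncol = length(families),
              dimnames = list(genomes, families))
  if (nrow(hits) > 0) {
    ri <- match(hits$genome_id, genomes)
    ci <- match(hits$family_id, families)
    ok <- !is.na(ri) & !is.na(ci)
    m[cbind(ri[ok], ci[ok])] <- 1L
  }
  m
}

#' Classify gene families as core, accessory or absent
#'
#' Prevalence of a family is the fraction of genomes carrying it (column
#' mean of the presence matrix). Families at or above
#' \code{core_min_fraction} are core; detected families below it are
#' accessory; undetected families are absent.
#'
#' @param matrix Binary presence matrix (genomes x families).
#' @param core_min_fraction Core threshold, inclusive. Default 0.9.
#' @return Data frame with columns \code{family_id}, \code{prevalence},
#'   \code{label}.
#' @export
classify_gene_prevalence <- function(matrix, core_min_fraction = 0.9) {
  prev <- colMeans(matrix)
  label <- ifelse(prev >= core_min_fraction & prev > 0, "core",
                  ifelse(prev > 0, "accessory", "absent"))
  data.frame(family_id = colnames(matrix), prevalence = unname(prev),
             label = unname(label), stringsAsFactors = FALSE)
}

#' Select genomes carrying a marker gene
#'
#' Genomes with at least one surviving hit for the marker family (e.g. the
#' \emph{ppk1} polyphosphate kinase family K00937) are retained; each is
#' mapped to the ORF of its best hit for downstream alignment/tree building.
#'
#' @param hits Surviving hit table.
#' @param marker_family Family id of the phylogenetic marker.
#' @return Data frame with columns \code{genome_id} and \code{orf_id} (the
#'   best-bitscore marker ORF per genome).
#' @export
select_marker_genomes <- function(hits, marker_family) {
  stopifnot(is.character(marker_family), length(marker_family) == 1)
  mk <- hits[hits$family_id == marker_family, , drop = FALSE]
  best <- best_hit_per_family(mk)
  data.frame(genome_id = best$genome_id, orf_id = best$orf_id,
             stringsAsFactors = FALSE)
}

#' Write a presence matrix as TSV
#'
#' @param matrix Binary matrix with genome rows and family columns.
#' @param path Output file.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- data.frame(genome_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence matrix written by [write_presence_matrix()]
#'
#' @param path TSV file with a \code{genome_id} column and one 0/1 column per
#'   family.
#' @return Integer 0/1 matrix.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (!all(m %in% c(0L, 1L))) stop("presence matrix cells must be 0/1: ", path)
  m
}
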
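AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
SPIII_PLUS1 <- c("F", "I", "L", "M", "V")

#' Survey configuration
#'
#' Thresholds of the major-pilin survey: the large-pilin mature-length
#' threshold (>= 166 aa), the redundancy-filter identity cutoff (> 0.90), the
#' N-terminal consensus conservation cutoff (>= 0.60) and the consensus
#' window (mature residues 1-55).
#'
#' @param large_threshold mature length (aa) at and above which a pilin is
#'   "large".
#' @param identity_cutoff pairwise identity above which sequences are
#'   clustered together.
#' @param consensus_cutoff fraction at and above which a position is called
#'   conserved.
#' @param nterm_window consensus window length (aa).
#' @return list of class `SurveyConfig`.
#' @export
survey_config <- function(large_threshold = 166, identity_cutoff = 0.90,
                          consensus_cutoff = 0.60, nterm_window = 55) {
  stopifnot(large_threshold >= 1, identity_cutoff > 0, identity_cutoff <= 1,
            consensus_cutoff > 0, consensus_cutoff <= 1, nterm_window >= 1)
  structure(list(large_threshold = as.integer(large_threshold),
                 identity_cutoff = identity_cutoff,
                 consensus_cutoff = consensus_cutoff,
                 nterm_window = as.integer(nterm_window)),
            class = "SurveyConfig")
}

#' Detect the class III signal peptide cleavage site
#'
#' Scans the first 60 residues for the prepilin-peptidase motif
#' `G-[F]-x-x-x-E` (cleaved between the Gly and the Phe; the mature pilin
#' starts at the Phe). A strict first pass requires Phe at +1; a fallback
#' pass admits the hydrophobic set F/I/L/M/V, since genuine prepilins can
#' deviate at +1. The first match wins.
#'
#' @param seq amino-acid string (prepilin), length >= 10; standard alphabet,
#'   `X` tolerated.
#' @return list with `index` (0-based position of the Gly) and `strict`
#'   (logical), or `NULL` when no motif is found.
#' @export
detect_spiii <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 10) stop("sequence shorter than 10 aa")
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    stop("non-amino-acid characters in sequence: ",
         paste(unique(chars[!(chars %in% AA_ALPHABET)]), collapse = ","))
  }
  last <- min(59, length(chars) - 6)
  hits_strict <- integer(0); hits_fall <- integer(0)
  for (i in 0:last) {
    if (chars[i + 1] == "G" && chars[i + 6] == "E") {
      p1 <- chars[i + 2]
      if (p1 == "F") hits_strict <- c(hits_strict, i)
      else if (p1 %in% SPIII_PLUS1) hits_fall <- c(hits_fall, i)
    }
  }
  if (length(hits_strict) > 0) return(list(index = hits_strict[1], strict = TRUE))
  if (length(hits_fall) > 0) return(list(index = hits_fall[1], strict = FALSE))
  NULL
}

#' Build a prepilin record table
#'
#' @param ids character vector of identifiers.
#' @param sequences character vector of prepilin sequences.
#' @param phylum,class_ optional taxonomy vectors.
#' @return data frame with columns `id`, `sequence`, `phylum`, `class`,
#'   `spiii_cleavage` (0-based Gly index or NA), `spiii_strict`,
#'   `mature_length`, `size_class` (NA until [classify_length()]).
#' @export
prepilin_records <- function(ids, sequences, phylum = NA, class_ = NA) {
  stopifnot(length(ids) == length(sequences))
  cleav <- lapply(sequences, function(s) tryCatch(detect_spiii(s),
                                                  error = function(e) NULL))
  idx <- vapply(cleav, function(h) if (is.null(h)) NA_integer_ else as.integer(h$index), 0L)
  strict <- vapply(cleav, function(h) if (is.null(h)) NA else h$strict, NA)
  data.frame(id = ids, sequence = sequences,
             phylum = rep_len(phylum, length(ids)),
             class = rep_len(class_, length(ids)),
             spiii_cleavage = idx, spiii_strict = strict,
             mature_length = nchar(sequences) - (idx + 1L),
             size_class = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify pilins by mature length
#'
#' The mature length is the prepilin length minus the signal peptide
#' (cleavage after the Gly, mature sequence starting at the +1 residue).
#' Pilins at or above the threshold are `large`, below it `standard`.
#' Records without a detected cleavage site stay `unclassified` and are
#' excluded from summaries (counted in the drop log).
#'
#' @param records data frame from [prepilin_records()].
#' @param cfg a [survey_config()].
#' @return The records with `mature_length` and `size_class` filled in.
#' @export
classify_length <- function(records, cfg = survey_config()) {
  has <- !is.na(records$spiii_cleavage)
  records$mature_length <- ifelse(has,
    nchar(records$sequence) - (records$spiii_cleavage + 1L), NA_integer_)
  records$size_class <- ifelse(!has, "unclassified",
    ifelse(records$mature_length >= cfg$large_threshold, "large", "standard"))
  records
}

# mature (signal-peptide-cleaved) sequence; numbering starts at the +1
# residue: position 1 = F, position 5 = conserved Glu, position 22 = Pro22
mature_sequence <- function(records) {
  ifelse(is.na(records$spiii_cleavage), NA_character_,
         substr(records$sequence, records$spiii_cleavage + 2L,
                nchar(records$sequence)))
}

aa_identity_submat <- function() {
  m <- matrix(0, length(AA_ALPHABET), length(AA_ALPHABET),
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- 1
  m
}

# vectorized global-alignment identity of one query against many references:
# matches / alignment columns under match 1 / mismatch 0 / gap open 1 /
# gap extend 0.5 scoring
pairwise_identity_many <- function(refs, query) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(refs), query, type = "global",
    substitutionMatrix = aa_identity_submat(),
    gapOpening = 1, gapExtension = 0.5)
  Biostrings::nmatch(aln) / Biostrings::width(Biostrings::alignedPattern(aln))
}

#' Greedy identity clustering (redundancy filter)
#'
#' Sequences are sorted by descending length, ties broken by identifier, and
#' processed greedily: each sequence joins the first retained representative
#' with global-alignment identity (matches / alignment columns; match 1,
#' mismatch 0, gap open 1, gap extend 0.5) strictly above `cutoff`, otherwise
#' it becomes a new representative. Deterministic and idempotent; the result
#' does not depend on the input order.
#'
#' @param records data frame with `id` and `sequence` columns.
#' @param cutoff identity cutoff (default 0.90; members have identity
#'   > cutoff to their representative).
#' @return list with `retained` (records subset of representatives) and
#'   `clusters` (data frame id, representative).
#' @export
cluster_identity <- function(records, cutoff = 0.90) {
  stopifnot(nrow(records) >= 1)
  ord <- order(-nchar(records$sequence), records$id)
  reps <- integer(0)
  assign <- character(nrow(records))
  for (i in ord) {
    placed <- FALSE
    if (length(reps) > 0) {
      # identity <= min(len)/max(len): representatives failing that bound
      # cannot exceed the cutoff and are skipped without aligning
      li <- nchar(records$sequence[i]); lr <- nchar(records$sequence[reps])
      cand <- reps[pmin(li, lr) / pmax(li, lr) > cutoff]
      if (length(cand) > 0) {
        idy <- pairwise_identity_many(records$sequence[cand],
                                      records$sequence[i])
        hit <- which(idy > cutoff)
        if (length(hit) > 0) {
          assign[i] <- records$id[cand[hit[1]]]
          placed <- TRUE
        }
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- records$id[i]
    }
  }
  list(retained = records[sort(reps), , drop = FALSE],
       clusters = data.frame(id = records$id, representative = assign,
                             stringsAsFactors = FALSE))
}

taxon_stats <- function(lengths, sizes, cfg) {
  n <- length(lengths)
  n_large <- sum(sizes == "large")
  data.frame(n = n, n_large = n_large,
             pct_large = round(100 * n_large / n),
             length_mean = mean(lengths),
             length_sd = sqrt(mean((lengths - mean(lengths))^2)),
             length_min = min(lengths), length_max = max(lengths))
}

#' Survey summary statistics, global and per taxon
#'
#' Mature-length statistics (mean, population SD, min, max) and large-pilin
#' counts with integer-rounded percentages, globally and per phylum and per
#' class. Taxa contributing less than 1% of the classified records are routed
#' to an `other` category. Unclassified records (no signal peptide) are
#' excluded and counted in `n_dropped`.
#'
#' @param records classified records ([classify_length()]).
#' @param cfg a [survey_config()].
#' @return list of class `SurveySummary`: `global` (one-row data frame),
#'   `per_phylum`, `per_class` (data frames), `n_dropped`.
#' @export
summarize_taxa <- function(records, cfg = survey_config()) {
  if (nrow(records) == 0) stop("no records")
  keep <- records$size_class %in% c("large", "standard")
  n_dropped <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no classified records (all lack a signal peptide)")
  per_level <- function(tax) {
    if (all(is.na(tax))) return(NULL)
    tax <- ifelse(is.na(tax), "unknown", tax)
    cnt <- table(tax)
    small <- names(cnt)[cnt < 0.01 * nrow(rec)]
    tax[tax %in% small] <- "other"
    out <- do.call(rbind, lapply(split(seq_len(nrow(rec)), tax), function(ix) {
      taxon_stats(rec$mature_length[ix], rec$size_class[ix], cfg)
    }))
    out <- cbind(taxon = rownames(out), out)
    rownames(out) <- NULL
    out[order(-out$n), , drop = FALSE]
  }
  structure(list(
    global = taxon_stats(rec$mature_length, rec$size_class, cfg),
    per_phylum = per_level(rec$phylum),
    per_class = per_level(rec$class),
    n_dropped = n_dropped
  ), class = "SurveySummary")
}

#' @export
print.SurveySummary <- function(x, ...) {
  g <- x$global
  cat(sprintf("SurveySummary: n = %d, large = %d (%d%%), mature length %.0f +/- %.0f aa (range %d-%d), %d dropped\n",
              g$n, g$n_large, g$pct_large, g$length_mean, g$length_sd,
              g$length_min, g$length_max, x$n_dropped))
  invisible(x)
}

#' N-terminal consensus profile of mature pilins
#'
#' Mature sequences are stacked by their shared N terminus (position 1 = the
#' Phe exposed by signal-peptide cleavage; no gapped alignment) and, for each
#' of the first `nterm_window` positions, the most frequent residue and its
#' frequency among sequences covering that position are reported. Positions
#' with frequency at or above `consensus_cutoff` are flagged conserved.
#'
#' @param records classified records with detected cleavage sites.
#' @param cfg a [survey_config()].
#' @return data frame with `position`, `residue`, `frequency`, `coverage`,
#'   `conserved`.
#' @export
consensus_profile <- function(records, cfg = survey_config()) {
  mat <- mature_sequence(records)
  mat <- mat[!is.na(mat)]
  if (length(mat) == 0) stop("no mature sequences")
  out <- lapply(seq_len(cfg$nterm_window), function(p) {
    res <- substr(mat, p, p)
    res <- res[nzchar(res)]
    if (length(res) == 0) {
      return(data.frame(position = p, residue = NA_character_, frequency = NA_real_,
                        coverage = 0L, conserved = FALSE))
    }
    tab <- sort(table(res), decreasing = TRUE)
    data.frame(position = p, residue = names(tab)[1],
               frequency = unname(tab[1]) / length(res),
               coverage = length(res),
               conserved = unname(tab[1]) / length(res) >= cfg$consensus_cutoff)
  })
  do.call(rbind, out)
}

#' Read a protein FASTA into id/sequence vectors
#' @param path FASTA path.
#' @return data frame with `id` (first token of header) and `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = vapply(strsplit(names(ss), "[[:space:]]+"), `[`, "", 1),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write id/sequence records as FASTA
#' @param records data frame with `id` and `sequence`.
#' @param path output path.
#' @export
write_fasta_sequences <- function(records, path) {
  ss <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Run the full survey pipeline
#'
#' FASTA + optional taxonomy TSV (columns id, phylum, class) in; signal
#' peptides detected, lengths classified, redundancy filtered, summaries and
#' consensus out.
#'
#' @param fasta path to prepilin FASTA.
#' @param taxonomy optional path to a taxonomy TSV.
#' @param cfg a [survey_config()].
#' @param cluster apply the identity redundancy filter (default TRUE).
#' @return list with `records`, `retained`, `summary`, `consensus`.
#' @export
run_survey <- function(fasta, taxonomy = NULL, cfg = survey_config(),
                       cluster = TRUE) {
  seqs <- read_fasta_sequences(fasta)
  phylum <- NA; class_ <- NA
  if (!is.null(taxonomy)) {
    tax <- read.delim(taxonomy, stringsAsFactors = FALSE)
    m <- match(seqs$id, tax$id)
    phylum <- tax$phylum[m]; class_ <- tax$class[m]
  }
  rec <- prepilin_records(seqs$id, seqs$sequence, phylum, class_)
  rec <- classify_length(rec, cfg)
  retained <- if (cluster) cluster_identity(rec, cfg$identity_cutoff)$retained else rec
  list(records = rec, retained = retained,
       summary = summarize_taxa(retained, cfg),
       consensus = consensus_profile(retained, cfg))
}
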
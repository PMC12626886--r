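#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. Peptides are
#' filtered to the observable length window — a length proxy for the
#' instrument's m/z range. Concatenating the unfiltered peptides (see
#' [tryptic_cleave()]) restores the input sequence.
#'
#' @param sequence protein sequence, one-letter amino-acid codes.
#' @param missed_cleavages number of allowed missed cleavage sites.
#' @param length_range observable peptide length window `c(min, max)`.
#' @return Character vector of distinct observable peptides. A warning is
#'   raised when the window excludes everything.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0,
                           length_range = c(6, 30)) {
  frags <- tryptic_cleave(sequence)
  peps <- frags
  if (missed_cleavages > 0) {
    for (mc in seq_len(missed_cleavages)) {
      if (length(frags) <= mc) break
      joined <- vapply(seq_len(length(frags) - mc), function(i) {
        paste(frags[i:(i + mc)], collapse = "")
      }, "")
      peps <- c(peps, joined)
    }
  }
  nc <- nchar(peps)
  out <- unique(peps[nc >= length_range[1] & nc <= length_range[2]])
  if (length(out) == 0) {
    warning("tryptic_digest(): length window excludes all peptides")
  }
  out
}

#' @rdname tryptic_digest
#' @export
tryptic_cleave <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("tryptic_cleave(): empty sequence")
  aa <- strsplit(sequence, "")[[1]]
  legal <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(unique(aa), legal)
  if (length(bad)) {
    stop("tryptic_cleave(): illegal amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1, n)] != "P"]
  starts <- c(1, cut_after + 1)
  ends <- c(cut_after, n)
  vapply(seq_along(starts), function(i) {
    paste(aa[starts[i]:ends[i]], collapse = "")
  }, "")
}

#' Exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`.
#'
#' @param n_observed distinct observed peptides (0..n_observable).
#' @param n_observable distinct observable peptides (>= 1).
#' @return emPAI value (>= 0).
#' @export
empai <- function(n_observed, n_observable) {
  stopifnot(length(n_observed) == length(n_observable))
  if (any(n_observable < 1) || any(n_observed < 0) ||
      any(n_observed > n_observable)) {
    stop("empai(): need 0 <= n_observed <= n_observable and n_observable >= 1")
  }
  10^(n_observed / n_observable) - 1
}

#' emPAI records from a peptide table
#'
#' Counts distinct observed peptides per protein and replicate against the
#' protein's observable tryptic peptides.
#'
#' @param table peptide `data.frame(protein_id, replicate, peptide)`.
#' @param protein_catalogue `data.frame(protein_id, sequence)`.
#' @param length_range observable window passed to [tryptic_digest()].
#' @return `data.frame(protein_id, replicate, n_observed, n_observable,
#'   empai)`.
#' @export
empai_table <- function(table, protein_catalogue, length_range = c(6, 30)) {
  reps <- sort(unique(table$replicate))
  if (length(reps) == 0) reps <- 1:3
  rows <- list()
  for (i in seq_len(nrow(protein_catalogue))) {
    pid <- protein_catalogue$protein_id[i]
    observable <- suppressWarnings(
      tryptic_digest(protein_catalogue$sequence[i], length_range = length_range))
    if (length(observable) == 0) next
    for (r in reps) {
      obs <- unique(table$peptide[table$protein_id == pid &
                                    table$replicate == r])
      obs <- intersect(obs, observable)
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = pid, replicate = r, n_observed = length(obs),
        n_observable = length(observable),
        empai = empai(length(obs), length(observable)))
    }
  }
  do.call(rbind, rows)
}

#' Replicate presence calls
#'
#' A protein is detected in a replicate iff at least `min_peptides`
#' distinct peptides were observed there (the deterministic stand-in for
#' probabilistic two-peptide validation).
#'
#' @param table peptide `data.frame(protein_id, replicate, peptide)`.
#' @param min_peptides distinct-peptide threshold (default 2).
#' @param n_replicates replicates in the design (for the `k/n` string).
#' @return `data.frame(protein_id, n_detected, presence)` with presence
#'   strings like `"2/3"`; `detected_in` is attached as a list column.
#' @export
presence_table <- function(table, min_peptides = 2, n_replicates = 3) {
  if (nrow(table) == 0) {
    return(data.frame(protein_id = character(), n_detected = integer(),
                      presence = character()))
  }
  counts <- stats::aggregate(
    list(n_pep = table$peptide),
    by = list(protein_id = table$protein_id, replicate = table$replicate),
    FUN = function(x) length(unique(x)))
  det <- counts[counts$n_pep >= min_peptides, , drop = FALSE]
  ids <- sort(unique(table$protein_id))
  detected_in <- lapply(ids, function(p) sort(det$replicate[det$protein_id == p]))
  out <- data.frame(protein_id = ids,
                    n_detected = vapply(detected_in, length, 1L))
  out$presence <- sprintf("%d/%d", out$n_detected, n_replicates)
  out$detected_in <- detected_in
  out
}

#' Read the packaged nucleoporin inventory fixture
#'
#' The packaged TSV transcribes the published per-replicate emPAI values,
#' their sd and the presence column for the 31 detected A. thaliana
#' nucleoporins. Replicate detection is derived from non-zero emPAI values
#' and cross-checked against the presence column.
#'
#' @param path fixture path; default the packaged table.
#' @return `data.frame` with emPAI columns plus derived `n_detected` and
#'   `presence`.
#' @export
read_empai_fixture <- function(path = system.file("extdata",
                                                  "atnup_empai_table.tsv",
                                                  package = "porekit",
                                                  mustWork = TRUE)) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  det <- (df$empai_1 > 0) + (df$empai_2 > 0) + (df$empai_3 > 0)
  stated <- as.integer(sub("/3$", "", df$presence))
  if (any(det != stated)) {
    warning("read_empai_fixture(): presence column disagrees with non-zero emPAI counts for: ",
            paste(df$protein[det != stated], collapse = ", "))
  }
  df$n_detected <- det
  df$protein_id <- df$protein
  df
}

#' Read the packaged nucleoporin catalogue
#'
#' @param path catalogue path; default the packaged list of currently
#'   reported A. thaliana nucleoporins.
#' @return `data.frame(protein, group)`.
#' @export
read_nup_catalogue <- function(path = system.file("extdata",
                                                  "atnup_catalogue.tsv",
                                                  package = "porekit",
                                                  mustWork = TRUE)) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Nucleoporin census
#'
#' Counts catalogue proteins detected in at least one replicate and builds
#' the per-presence histogram. Proteins outside the catalogue are ignored.
#'
#' @param presence a presence table (`protein_id`, `n_detected`) — from
#'   [presence_table()] or [read_empai_fixture()].
#' @param nup_catalogue character vector of catalogue protein ids, or a
#'   `data.frame` with a `protein` column.
#' @param n_replicates replicates in the design.
#' @return `list(n_detected, histogram, detected, undetected)`.
#' @export
census <- function(presence, nup_catalogue, n_replicates = 3) {
  cat_ids <- if (is.data.frame(nup_catalogue)) nup_catalogue$protein
             else as.character(nup_catalogue)
  p <- presence[presence$protein_id %in% cat_ids, , drop = FALSE]
  detected <- p$protein_id[p$n_detected >= 1]
  hist <- table(factor(sprintf("%d/%d", p$n_detected[p$n_detected >= 1],
                               n_replicates),
                       levels = sprintf("%d/%d", 1:n_replicates, n_replicates)))
  list(n_detected = length(detected), histogram = hist,
       detected = sort(detected),
       undetected = sort(setdiff(cat_ids, detected)))
}

#' Y-complex membership overlap between two organisms
#'
#' Intersects two member sets after mapping functional homologues (by
#' default the packaged map sends the plant ELYS homologue HOS1 to ELYS).
#'
#' @param set_A,set_B character vectors of member names.
#' @param homologue_map named character vector/list mapping names in
#'   `set_A` to their homologues in `set_B`'s nomenclature.
#' @return `list(shared, count, only_A, only_B)`.
#' @export
y_complex_overlap <- function(set_A, set_B, homologue_map = list()) {
  stopifnot(length(set_A) > 0, length(set_B) > 0)
  mapped <- vapply(set_A, function(s) {
    if (!is.null(homologue_map[[s]])) homologue_map[[s]] else s
  }, "")
  shared <- intersect(mapped, set_B)
  list(shared = sort(shared), count = length(shared),
       only_A = sort(setdiff(mapped, set_B)),
       only_B = sort(setdiff(set_B, mapped)))
}

#' Read the packaged Y-complex member sets
#'
#' @return `list(arabidopsis, human, homologue_map)`.
#' @export
y_complex_sets <- function() {
  jsonlite::fromJSON(system.file("extdata", "y_complex_members.json",
                                 package = "porekit", mustWork = TRUE))
}

#' Read protein sequences from FASTA
#'
#' Minimal FASTA reader for catalogue construction; headers are truncated
#' at the first whitespace.
#'
#' @param path FASTA file.
#' @return `data.frame(protein_id, sequence)`.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("read_protein_fasta(): no FASTA headers found")
  idx <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(seq_along(ids), function(i) {
    paste(lines[idx == i & !hdr], collapse = "")
  }, "")
  data.frame(protein_id = ids, sequence = toupper(seqs))
}
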
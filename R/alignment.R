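## seq_io: alignments, group tables, haplotype collapsing.

#' Construct a haplotype alignment
#'
#' An alignment is the raw material of every statistic in the package: a set
#' of equal-length DNA sequences (one per sample) with unique sample
#' identifiers and, optionally, a sample-to-group assignment used for
#' per-haplogroup analyses.
#'
#' @param sequences Character vector of aligned sequences (strings over
#'   `A`, `C`, `G`, `T`, `N`, `-`; lower case accepted), or a character
#'   matrix with one row per sample and one column per site.
#' @param ids Sample identifiers; defaults to `names(sequences)` (or
#'   `rownames` for a matrix input). Must be unique and non-empty.
#' @param groups Optional named character vector mapping sample id to group
#'   label. Samples absent from the mapping get `NA`.
#'
#' @return An object of class `hap_alignment`: a list with elements `seq`
#'   (character matrix, rows = samples), `ids`, `groups`, `n` and `k`
#'   (alignment length in base pairs).
#' @export
#' @examples
#' aln <- hap_alignment(c(s1 = "ACGTACGTAA", s2 = "ACGTACGTTA"))
#' aln$k
hap_alignment <- function(sequences, ids = NULL, groups = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (is.null(ids)) ids <- names(sequences)
    if (is.null(ids)) abort_input("sample ids are required (name the sequences or pass `ids`)")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      abort_input(sprintf(
        "aligned sequences must all have the same length; found lengths {%s}",
        paste(sort(unique(lens)), collapse = ", ")
      ))
    }
    mat <- matrix(toupper(unlist(strsplit(sequences, "", fixed = TRUE))),
      nrow = length(sequences), byrow = TRUE
    )
  }
  mat[] <- toupper(mat)
  ids <- as.character(ids)
  if (length(ids) != nrow(mat)) abort_input("one id per sequence required")
  if (anyDuplicated(ids)) {
    abort_input(sprintf(
      "duplicate sample ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if (ncol(mat) == 0L || nrow(mat) == 0L) abort_input("empty alignment")
  bad <- setdiff(unique(as.vector(mat)), c(.BASES, .MISSING))
  if (length(bad)) {
    abort_input(sprintf(
      "unknown residue symbol(s) in alignment: %s (allowed: A,C,G,T,N,-)",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  rownames(mat) <- ids
  grp <- NULL
  if (!is.null(groups)) {
    grp <- as.character(groups[ids])
    names(grp) <- ids
  }
  structure(
    list(seq = mat, ids = ids, groups = grp, n = nrow(mat), k = ncol(mat)),
    class = "hap_alignment"
  )
}

#' Read an aligned FASTA file (optionally with a group table)
#'
#' The FASTA description line up to the first whitespace is taken as the
#' sample id; wrapped and single-line sequence records are both accepted.
#' The group table is a two-column TSV (`sample_id`, `group`); a header row
#' is detected and skipped when its first field matches no sample id.
#' Samples listed in the table but absent from the alignment are warned
#' about and ignored.
#'
#' @param fasta Path to an aligned FASTA file.
#' @param groups Optional path to a tab-separated group table.
#' @return A [hap_alignment].
#' @export
read_alignment <- function(fasta, groups = NULL) {
  if (!file.exists(fasta)) abort_input(sprintf("FASTA file not found: %s", fasta))
  dna <- ape::read.FASTA(fasta)
  if (!length(dna)) abort_input(sprintf("no sequences in %s", fasta))
  ids <- sub("\\s.*$", "", names(dna))
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    abort_input(sprintf(
      "sequences in %s are not aligned (lengths %s)",
      fasta, paste(sort(unique(lens)), collapse = ", ")
    ))
  }
  seqs <- vapply(as.character(dna), function(x) paste0(x, collapse = ""), character(1))
  grp <- if (!is.null(groups)) read_group_table(groups, ids = ids) else NULL
  hap_alignment(toupper(seqs), ids = ids, groups = grp)
}

#' Read a two-column sample-to-group table
#'
#' @param path TSV file with columns (sample_id, group); header optional.
#' @param ids Optional character vector of known sample ids, used both for
#'   header detection and to warn about unknown samples.
#' @return Named character vector mapping sample id to group label.
#' @export
read_group_table <- function(path, ids = NULL) {
  if (!file.exists(path)) abort_input(sprintf("group table not found: %s", path))
  tab <- utils::read.table(path,
    sep = "\t", header = FALSE, colClasses = "character",
    quote = "", comment.char = "", fileEncoding = "UTF-8"
  )
  if (ncol(tab) < 2L) abort_input("group table needs two tab-separated columns (sample_id, group)")
  tab <- tab[, 1:2]
  looks_header <- tolower(tab[1, 1]) %in% c("sample", "sample_id", "id") ||
    (!is.null(ids) && !(tab[1, 1] %in% ids))
  if (nrow(tab) > 0L && looks_header && !is.null(ids) && !(tab[1, 1] %in% ids)) {
    tab <- tab[-1, , drop = FALSE]
  } else if (nrow(tab) > 0L && is.null(ids) && tolower(tab[1, 1]) %in% c("sample", "sample_id", "id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (!is.null(ids)) {
    unknown <- setdiff(tab[, 1], ids)
    if (length(unknown)) {
      warning(sprintf(
        "group table lists %d sample(s) not in the alignment (ignored): %s",
        length(unknown), paste(utils::head(unknown, 5), collapse = ", ")
      ))
      tab <- tab[tab[, 1] %in% ids, , drop = FALSE]
    }
  }
  stats::setNames(as.character(tab[, 2]), tab[, 1])
}

#' Write an alignment to FASTA
#'
#' @param aln A [hap_alignment].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  dna <- ape::as.DNAbin(aln$seq)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Write a group table to TSV
#'
#' @param aln A [hap_alignment] with group labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(aln$groups)) abort_input("alignment has no group labels")
  utils::write.table(
    data.frame(sample_id = aln$ids, group = unname(aln$groups)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Restrict an alignment to one group
#'
#' @param aln A [hap_alignment] with group labels.
#' @param group Group label to keep.
#' @return A [hap_alignment] containing only the members of `group`; the
#'   alignment length is unchanged.
#' @export
subset_by_group <- function(aln, group) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (is.null(aln$groups)) abort_input("alignment has no group labels")
  if (!(group %in% aln$groups)) {
    abort_input(sprintf("unknown group label: %s", sQuote(group)))
  }
  keep <- aln$ids[!is.na(aln$groups) & aln$groups == group]
  hap_alignment(aln$seq[keep, , drop = FALSE],
    ids = keep,
    groups = aln$groups[keep]
  )
}

#' Group labels present in an alignment
#' @param aln A [hap_alignment].
#' @return Character vector of group labels (first-occurrence order), or
#'   `NULL` when the alignment carries no labels.
#' @export
group_levels <- function(aln) {
  if (is.null(aln$groups)) return(NULL)
  g <- aln$groups[!is.na(aln$groups)]
  unique(unname(g))
}

## Can two sequences be the same haplotype? They must agree at every site
## where both are unambiguous; N/- never separate haplotypes.
.compatible <- function(a, b) {
  ok <- (a %in% .BASES) & (b %in% .BASES)
  all(a[ok] == b[ok])
}

#' Collapse an alignment into haplotypes
#'
#' Sequences are grouped in first-occurrence order: each sample joins the
#' first existing haplotype whose representative sequence matches it at
#' every site where both are unambiguous (N and `-` are treated as missing
#' and never separate haplotypes); otherwise it founds a new haplotype
#' whose representative is its own sequence.
#'
#' @param aln A [hap_alignment].
#' @return An object of class `hap_table`: list with `sequences`
#'   (representative sequence matrix, rows = haplotypes `H1`, `H2`, ...),
#'   `frequency`, `members` (list of sample ids), `group` (label of the
#'   first member, `NA` if unlabelled), `n`, `k` and `k_obs` (number of
#'   distinct haplotypes).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  reps <- list()
  members <- list()
  for (i in seq_len(aln$n)) {
    s <- aln$seq[i, ]
    hit <- 0L
    for (j in seq_along(reps)) {
      if (.compatible(reps[[j]], s)) {
        hit <- j
        break
      }
    }
    if (hit) {
      members[[hit]] <- c(members[[hit]], aln$ids[i])
    } else {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- aln$ids[i]
    }
  }
  k_obs <- length(reps)
  mat <- do.call(rbind, reps)
  rownames(mat) <- paste0("H", seq_len(k_obs))
  grp <- rep(NA_character_, k_obs)
  if (!is.null(aln$groups)) {
    grp <- vapply(members, function(m) unname(aln$groups[m[1]]), character(1))
  }
  structure(
    list(
      sequences = mat,
      frequency = vapply(members, length, integer(1)),
      members = members,
      group = grp,
      n = aln$n, k = aln$k, k_obs = k_obs
    ),
    class = "hap_table"
  )
}

#' Expand a haplotype table back into an alignment
#'
#' Inverse of [collapse_haplotypes()] up to haplotype representatives: each
#' haplotype is repeated once per member, labelled with the member ids.
#'
#' @param table A `hap_table`.
#' @return A [hap_alignment].
#' @export
expand_haplotypes <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  idx <- rep(seq_len(table$k_obs), table$frequency)
  ids <- unlist(table$members)
  mat <- table$sequences[idx, , drop = FALSE]
  rownames(mat) <- ids
  grp <- NULL
  if (!all(is.na(table$group))) {
    grp <- stats::setNames(rep(table$group, table$frequency), ids)
  }
  hap_alignment(mat, ids = ids, groups = grp)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf(
    "Haplotype alignment: %d sequences x %d bp%s\n",
    x$n, x$k,
    if (!is.null(x$groups)) {
      sprintf(" (%d groups)", length(group_levels(x)))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf(
    "Haplotype table: %d haplotypes from %d samples (%d bp)\n",
    x$k_obs, x$n, x$k
  ))
  fr <- sort(x$frequency, decreasing = TRUE)
  cat("  frequencies:", paste(utils::head(fr, 12), collapse = " "),
    if (length(fr) > 12) "...\n" else "\n")
  invisible(x)
}
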
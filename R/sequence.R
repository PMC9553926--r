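#' Modified RNA sequence
#'
#' An ordered list of residue codes with 1-based positions. Positions are
#' linear sequence coordinates (no Sprinzl alignment); a windowed
#' subsequence keeps the parent's position labels so that "position 32"
#' still names the same residue after oligo protection.
#'
#' @param codes Character vector of residue codes (each resolvable in
#'   [modification_table()]).
#' @param id Sequence identifier.
#' @param positions Integer positions; defaults to `1:length(codes)`.
#' @return An object of class `mod_rna_seq`.
#' @export
mod_rna_seq <- function(codes, id = "seq", positions = seq_along(codes)) {
  codes <- as.character(codes)
  positions <- as.integer(positions)
  if (length(codes) != length(positions))
    stop("codes and positions differ in length")
  if (length(positions) && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  bad <- !codes %in% modification_table()$code
  if (any(bad))
    stop("unknown residue code(s): ", paste(unique(codes[bad]), collapse = ", "))
  structure(list(id = id, codes = codes, positions = positions),
            class = "mod_rna_seq")
}

#' @export
length.mod_rna_seq <- function(x) length(x$codes)

#' @export
print.mod_rna_seq <- function(x, ...) {
  cat("<mod_rna_seq> ", x$id, ": ", length(x), " residues",
      if (length(x)) paste0(" (positions ", min(x$positions), "-",
                            max(x$positions), ")"), "\n", sep = "")
  mods <- x$codes[!x$codes %in% c("A", "C", "G", "U")]
  if (length(mods)) {
    at <- x$positions[!x$codes %in% c("A", "C", "G", "U")]
    cat("  modifications: ",
        paste(paste0(mods, at), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

code_at <- function(seq, position) {
  i <- match(position, seq$positions)
  if (is.na(i)) stop("position ", position, " not in sequence ", seq$id)
  seq$codes[i]
}

set_code_at <- function(seq, position, code) {
  i <- match(position, seq$positions)
  if (is.na(i)) stop("position ", position, " not in sequence ", seq$id)
  seq$codes[i] <- code
  seq
}

#' Build a modified sequence from a base sequence and a modification profile
#'
#' Substitutes modification codes at stated 1-based positions of a canonical
#' RNA string, checking each profile entry against the declared parent base
#' of the code (e.g. `D` at a position requires a `U` there; `Y` accepts `U`
#' or `C`, since pseudouridine can arise by editing of either).
#'
#' @param sequence Canonical RNA string (A/C/G/U; T is read as U) or a
#'   character vector of single bases.
#' @param profile Data frame with columns `position` and `code`, or a list
#'   of `(position, code)` pairs; may be empty.
#' @param id Sequence identifier.
#' @return A [mod_rna_seq()].
#' @examples
#' parse_modified_sequence("AGAC", data.frame(position = integer(),
#'                                            code = character()))
#' @export
parse_modified_sequence <- function(sequence, profile = NULL, id = "seq") {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  sequence[sequence == "T"] <- "U"
  bad <- !sequence %in% c("A", "C", "G", "U")
  if (any(bad))
    stop("non-canonical base(s) in sequence: ",
         paste(unique(sequence[bad]), collapse = ", "),
         " (modifications belong in the profile)")
  codes <- sequence
  profile <- normalize_profile(profile)
  tab <- modification_table()
  for (k in seq_len(nrow(profile))) {
    pos <- profile$position[k]
    code <- profile$code[k]
    if (is.na(pos) || pos < 1L || pos > length(codes))
      stop("profile position ", pos, " out of range 1..", length(codes))
    if (!code %in% tab$code)
      stop("unknown modification code '", code, "' at position ", pos)
    parents <- strsplit(mod_row(code, tab)$parent, ",")[[1]]
    if (length(parents) && !codes[pos] %in% parents)
      stop("code '", code, "' at position ", pos, " requires parent base ",
           paste(parents, collapse = "/"), " but sequence has ", codes[pos])
    codes[pos] <- code
  }
  mod_rna_seq(codes, id = id)
}

normalize_profile <- function(profile) {
  if (is.null(profile))
    return(data.frame(position = integer(), code = character()))
  if (is.data.frame(profile)) {
    stopifnot(all(c("position", "code") %in% names(profile)))
    return(data.frame(position = as.integer(profile$position),
                      code = as.character(profile$code)))
  }
  # list of (position, code) pairs
  data.frame(position = vapply(profile, function(p) as.integer(p[[1]]), 1L),
             code = vapply(profile, function(p) as.character(p[[2]]), ""))
}

#' Read a modified sequence from FASTA plus a profile TSV
#'
#' @param fasta Path to a FASTA file; the first record is used.
#' @param profile_tsv Optional path to a TSV with header
#'   `position<TAB>code`.
#' @return A [mod_rna_seq()].
#' @export
read_modified_sequence <- function(fasta, profile_tsv = NULL) {
  recs <- seqinr::read.fasta(fasta, as.string = TRUE, forceDNAtolower = FALSE)
  if (!length(recs)) stop("no FASTA records in ", fasta)
  base <- as.character(recs[[1]])
  profile <- if (!is.null(profile_tsv)) read_profile(profile_tsv)
  parse_modified_sequence(base, profile, id = names(recs)[1])
}

#' @rdname read_modified_sequence
#' @param path Path to a `position<TAB>code` TSV.
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "code") %in% names(tab)))
  tab
}

#' Write a modified sequence as FASTA (canonical parents) plus profile TSV
#'
#' The FASTA carries the canonical parent base at each modified position
#' (first listed parent); the profile TSV carries the modification codes.
#'
#' @param seq A [mod_rna_seq()].
#' @param fasta,profile_tsv Output paths.
#' @export
write_modified_sequence <- function(seq, fasta, profile_tsv) {
  tab <- modification_table()
  parents <- vapply(seq$codes, function(code) {
    p <- strsplit(mod_row(code, tab)$parent, ",")[[1]][1]
    if (is.na(p) || !nzchar(p)) code else p
  }, "")
  seqinr::write.fasta(paste(parents, collapse = ""), names = seq$id,
                      file.out = fasta, as.string = TRUE)
  is_mod <- !seq$codes %in% c("A", "C", "G", "U")
  utils::write.table(
    data.frame(position = seq$positions[is_mod], code = seq$codes[is_mod]),
    profile_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(seq)
}
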
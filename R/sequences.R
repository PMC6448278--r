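#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A<->U, C<->G) of a 5'->3' sequence, reversed, so
#' the result is again written 5'->3'.
#'
#' @param seq Character vector of sequences over \{A,C,G,U\}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGU")        # palindromic tag
#' reverse_complement("CUCGACAGAU")  # "AUCUGUCGAG"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGU]", seq)))
    stop("sequence contains symbols outside {A,C,G,U}")
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Is a tag palindromic?
#'
#' A tag is usable by the tag-recognition mechanism only when it equals its
#' own reverse complement, so that the reverse-tag and the REP's
#' tag-recognizing domain all share the tag's sequence.
#'
#' @param tag A single sequence.
#' @return Logical.
#' @export
is_palindromic_tag <- function(tag) {
  identical(reverse_complement(tag), tag)
}

#' Classify a strand's functional roles
#'
#' Applies the tag mechanism to one or more strands. With tag `t`, REP
#' catalytic domain `R` and NSR catalytic domain `S`:
#' \describe{
#'   \item{rep_functional}{the strand begins with `t` (the tag-recognizing
#'     domain) immediately followed by `R`.}
#'   \item{rep_spreadable}{additionally ends with a 3' reverse-tag (which,
#'     the tag being palindromic, reads `t` as well), with no overlap into
#'     the catalytic domain: `t + R + ... + t`.}
#'   \item{nsr_functional}{contains `S` anywhere.}
#'   \item{nsr_spreadable}{is exactly `t + S + t`.}
#'   \item{parasite}{begins and ends with `t` (length at least two tags) but
#'     carries no catalytic domain — neither `R` nor `S`, nor their reverse
#'     complements. Complementary strands of the ribozymes, which are
#'     obligatory replication intermediates rather than freeloaders, are
#'     therefore not counted as parasites.}
#'   \item{plain}{none of the above.}
#' }
#'
#' @param seq Character vector of strand sequences (5'->3').
#' @param params An `rw_params` object supplying `CS_REP`, `CS_NSR`,
#'   `CS_Tag`.
#' @return For a single sequence, a named logical vector (the role set); for
#'   several, a data.frame with one row per strand.
#' @examples
#' p <- default_params()
#' classify_strand("ACGUCUCGACAGAUACGU", p)  # spreadable REP
#' classify_strand("ACGUACGU", p)            # minimal parasite
#' @export
classify_strand <- function(seq, params = default_params()) {
  t <- params$CS_Tag; R <- params$CS_REP; S <- params$CS_NSR
  if (!is_palindromic_tag(t)) stop("tag not palindromic")
  one <- function(s) {
    n <- nchar(s)
    tl <- nchar(t)
    starts_tag <- startsWith(s, t)
    ends_tag <- endsWith(s, t)
    rep_fun <- startsWith(s, paste0(t, R))
    rep_spr <- rep_fun && ends_tag && n >= nchar(t) + nchar(R) + nchar(t)
    nsr_fun <- grepl(S, s, fixed = TRUE)
    nsr_spr <- identical(s, paste0(t, S, t))
    has_domain <- rep_fun || nsr_fun ||
      grepl(R, s, fixed = TRUE) ||
      grepl(reverse_complement(R), s, fixed = TRUE) ||
      grepl(reverse_complement(S), s, fixed = TRUE)
    parasite <- starts_tag && ends_tag && n >= 2L * tl && !has_domain
    plain <- !(rep_fun || nsr_fun || parasite)
    c(rep_functional = rep_fun, rep_spreadable = rep_spr,
      nsr_functional = nsr_fun, nsr_spreadable = nsr_spr,
      parasite = parasite, plain = plain)
  }
  if (length(seq) == 1L) return(one(seq))
  out <- t(vapply(seq, one, logical(6)))
  rownames(out) <- NULL
  data.frame(seq = seq, out, stringsAsFactors = FALSE)
}

#' Minimal role-defining sequences under a parameter set
#'
#' Constructs, from the configured domain and tag sequences, the shortest
#' strand realizing each role: functional REP (`tag + REP domain`),
#' spreadable REP (`tag + REP domain + tag`), functional NSR (the bare
#' domain), spreadable NSR (`tag + NSR domain + tag`), and the minimal
#' parasite (`tag + tag`). With the default 10-nt domains and 4-nt tag the
#' lengths are 14, 18, 10, 18 and 8 nt.
#'
#' @param params An `rw_params` object.
#' @return Named list of sequences.
#' @export
minimal_sequences <- function(params = default_params()) {
  t <- params$CS_Tag
  list(rep_functional = paste0(t, params$CS_REP),
       rep_spreadable = paste0(t, params$CS_REP, t),
       nsr_functional = params$CS_NSR,
       nsr_spreadable = paste0(t, params$CS_NSR, t),
       parasite = paste0(t, t))
}

#' Export strands as FASTA
#'
#' Debugging helper: writes strand sequences (U alphabet) to a FASTA file.
#' Requires the `seqinr` package.
#'
#' @param seqs Character vector of sequences.
#' @param path Output path.
#' @param names Optional sequence names (default `strand_1`, ...).
#' @export
export_strands_fasta <- function(seqs, path, names = NULL) {
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("seqinr is required for FASTA export")
  if (is.null(names)) names <- paste0("strand_", seq_along(seqs))
  seqinr::write.fasta(as.list(seqs), names = names, file.out = path,
                      as.string = TRUE)
  invisible(path)
}

#' Import strands from FASTA
#'
#' @param path FASTA file path.
#' @return Character vector of uppercase sequences, named by record.
#' @export
import_strands_fasta <- function(path) {
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("seqinr is required for FASTA import")
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(x) as.character(x)[1], ""))
  names(out) <- names(recs)
  out
}
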
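#' Plain-text dump of all duplex states
#'
#' Renders every template complex as an alignment block: the template
#' written 5'->3' on top, each aligned partner (substrate, growing product,
#' or the bound REP's recognition domain) drawn beneath at its register,
#' reversed so paired positions line up column-wise.
#'
#' @param sim An `rw_sim` object.
#' @param max_blocks Cap on the number of complexes printed.
#' @return The text lines, invisibly (also printed).
#' @export
dump_duplex_alignments <- function(sim, max_blocks = 50) {
  cx <- cpp_complexes(sim$ptr)
  if (!nrow(cx)) {
    cat("no template complexes\n")
    return(invisible(character()))
  }
  lines <- character()
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (id in unique(cx$complex)[seq_len(min(max_blocks,
                                            length(unique(cx$complex))))]) {
    rows <- cx[cx$complex == id, ]
    hdr <- sprintf("complex %d room %d%s", id, rows$room[1],
                   if (rows$in_cell[1]) " (protocell)" else "")
    tpl <- rows$template[1]
    lines <- c(lines, hdr, paste0("5'-", tpl, "-3'  (template)"))
    for (i in seq_len(nrow(rows))) {
      if (rows$kind[i] %in% c("bare")) next
      if (rows$kind[i] == "bound_rep") {
        lines <- c(lines, sprintf("   REP bound: %s", rows$partner[i]))
        next
      }
      pad <- strrep(" ", rows$offset[i])
      lines <- c(lines, sprintf("3'-%s%s-5'  (%s)", pad,
                                rev_str(rows$partner[i]), rows$kind[i]))
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
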
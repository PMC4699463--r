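# Dot-bracket bulge counting. The number of non-canonical (unpaired-in-helix)
# regions of an RNA secondary structure is the working estimate of the number
# of aminoglycoside binding sites, which in turn sets the site multiplicity of
# the displacement assay.

#' Count bulge and internal-loop regions of a dot-bracket structure
#'
#' Counts maximal unpaired regions enclosed within a helix: bulges, internal
#' loops (a two-sided internal loop counts once) and multibranch-loop spacers.
#' Hairpin loops, exterior/dangling ends and the `&` strand break of a duplex
#' are excluded; `&` is a region terminator, never an unpaired base.
#'
#' Concretely, every base pair closes a loop (the positions directly inside it,
#' jumping over child helices). A loop is counted when it contains at least
#' one unpaired base *and* at least one child helix; a loop with no child
#' helix is a hairpin (or a duplex open end) and is not counted.
#'
#' @param structure Dot-bracket string over `(`, `)`, `.` and optionally `&`
#'   joining two strands.
#' @return Integer number of enclosed unpaired regions.
#' @export
count_bulge_regions <- function(structure) {
  if (!is.character(structure) || length(structure) != 1L || is.na(structure))
    parse_error("'structure' must be a single string")
  ch <- strsplit(structure, "")[[1L]]
  bad <- which(!ch %in% c("(", ")", ".", "&"))
  if (length(bad) > 0L)
    parse_error(sprintf("invalid character '%s' at position %d",
                        ch[bad[1L]], bad[1L]))
  n <- length(ch)
  pair <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        parse_error(sprintf("unbalanced ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    }
  }
  if (length(stack) > 0L)
    parse_error(sprintf("unbalanced '(' at position %d", stack[length(stack)]))

  count <- 0L
  for (i in seq_len(n)) {
    if (ch[i] != "(") next
    j <- pair[i]
    unpaired <- 0L
    children <- 0L
    k <- i + 1L
    while (k < j) {
      if (ch[k] == "(") {
        children <- children + 1L
        k <- pair[k] + 1L
      } else {
        if (ch[k] == ".") unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (unpaired > 0L && children > 0L) count <- count + 1L
  }
  count
}
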
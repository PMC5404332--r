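#' Canonical module color sequence
#'
#' Modules are conventionally named by a fixed color sequence in decreasing
#' size order, with `"grey"` reserved for unassigned genes. This returns the
#' first `n` names of that sequence.
#'
#' @param n Number of color names requested.
#' @return Character vector of length `n`; positions beyond the built-in
#'   palette fall back to `"module_<k>"`.
#' @export
module_colors <- function(n) {
  pal <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
  )
  if (n <= length(pal)) return(pal[seq_len(n)])
  c(pal, paste0("module_", seq.int(length(pal) + 1L, n)))
}

#' Name size-ranked module labels by the canonical color sequence
#'
#' @param labels Integer vector of module labels (0 = unassigned), named by
#'   gene id. Labels need not be contiguous.
#' @return Character vector of color names, same names as `labels`;
#'   unassigned genes get `"grey"`.
#' @export
assign_colors <- function(labels) {
  stopifnot(is.numeric(labels))
  out <- rep("grey", length(labels))
  names(out) <- names(labels)
  mods <- setdiff(unique(labels), 0L)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    mods <- mods[order(-sizes, mods)]
    cols <- module_colors(length(mods))
    for (i in seq_along(mods)) out[labels == mods[i]] <- cols[i]
  }
  out
}
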
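# Newick tree IO. Trees are ape "phylo" objects throughout the package;
# internal-node bootstrap supports live in node.label as integer percents.

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick reader/writer that add an upfront
#' balance check (reporting the character position of the first unbalanced
#' parenthesis) and write branch lengths with 10 significant digits so that
#' `read_newick(write_newick(t))` reproduces topology, lengths and internal
#' support labels.
#'
#' @param path Path to a Newick file (for `read_newick`) or output path
#'   (for `write_newick`; `NULL` returns the Newick string).
#' @param tree An ape `phylo` object.
#' @return `read_newick`: a `phylo`. `write_newick`: the Newick text,
#'   invisibly when written to a file.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_balance(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop_format("could not parse Newick text in %s", path)
  tr
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  neg <- which(depth < 0)
  if (length(neg)) {
    stop_format("unbalanced ')' at character %d of Newick text", neg[1])
  }
  if (length(depth) && depth[length(depth)] != 0) {
    stop_format("unbalanced '(' in Newick text: %d unclosed at end",
                depth[length(depth)])
  }
  invisible(txt)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
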
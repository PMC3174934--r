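fmt_num <- function(x, fmt) ifelse(is.na(x), "NA", sprintf(fmt, x))

#' Summary table of scored metagroups
#'
#' One row per metagroup: id, gene and element counts, scores, and the
#' sorted `;`-joined gene and source-prefixed term lists.
#'
#' @param groups List of scored `Metagroup`s.
#' @return A data.frame.
#' @export
metagroup_table <- function(groups) {
  stopifnot(all(vapply(groups, inherits, TRUE, "Metagroup")))
  data.frame(
    metagroup_id = vapply(groups, `[[`, "", "metagroup_id"),
    n_genes = vapply(groups, function(g) length(g$union_genes), 0L),
    n_genetermsets = vapply(groups, function(g) length(g$elements), 0L),
    adjusted_p = vapply(groups, `[[`, 0, "adjusted_p"),
    raw_p = vapply(groups, `[[`, 0, "raw_p"),
    silhouette = vapply(groups, `[[`, 0, "silhouette"),
    diameter = vapply(groups, `[[`, 0, "diameter"),
    similarity_coefficient =
      vapply(groups, `[[`, 0, "similarity_coefficient"),
    genes = vapply(groups, function(g)
      paste(sort(g$union_genes), collapse = ";"), ""),
    terms = vapply(groups, function(g)
      paste(sort(g$union_terms), collapse = ";"), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-format element table of scored metagroups
#'
#' One row per (metagroup, GeneTerm-set) pair.
#'
#' @param groups List of `Metagroup`s.
#' @return A data.frame with metagroup_id, element_id, p_value, genes,
#'   terms.
#' @export
element_table <- function(groups) {
  rows <- lapply(groups, function(g)
    data.frame(
      metagroup_id = g$metagroup_id,
      element_id = vapply(g$elements, `[[`, "", "element_id"),
      p_value = vapply(g$elements, `[[`, 0, "p_value"),
      genes = vapply(g$elements, function(e)
        paste(sort(e$genes), collapse = ";"), ""),
      terms = vapply(g$elements, function(e)
        paste(sort(e$terms), collapse = ";"), ""),
      row.names = NULL, stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the metagroup report TSV
#'
#' Stable column order, fixed float precision, lexicographically sorted
#' `;`-joined gene/term lists: identical inputs produce byte-identical
#' files.
#'
#' @param groups List of scored `Metagroup`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metagroup_report <- function(groups, path) {
  tab <- metagroup_table(groups)
  header <- paste(names(tab), collapse = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) paste(
    tab$metagroup_id[i], tab$n_genes[i], tab$n_genetermsets[i],
    fmt_num(tab$adjusted_p[i], "%.4e"), fmt_num(tab$raw_p[i], "%.4e"),
    fmt_num(tab$silhouette[i], "%.4f"), fmt_num(tab$diameter[i], "%.4f"),
    fmt_num(tab$similarity_coefficient[i], "%.4f"),
    tab$genes[i], tab$terms[i], sep = "\t"), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}

write_element_report <- function(groups, path) {
  tab <- element_table(groups)
  header <- "metagroup_id\telement_id\tp_value\tgenes\tterms"
  rows <- if (is.null(tab) || !nrow(tab)) character(0) else
    vapply(seq_len(nrow(tab)), function(i) paste(
      tab$metagroup_id[i], tab$element_id[i],
      fmt_num(tab$p_value[i], "%.4e"), tab$genes[i], tab$terms[i],
      sep = "\t"), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}
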
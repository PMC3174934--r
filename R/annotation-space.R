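#' Annotation space: a term-to-gene catalog for one source and organism
#'
#' An `AnnotationSpace` bundles the term -> gene-set map of one annotation
#' source (e.g. `"GO-BP"`, `"KEGG"`, `"InterPro"`) for one organism, together
#' with the gene universe against which per-term frequencies are computed.
#' Gene identifiers are opaque, case-sensitive strings; leading/trailing
#' whitespace is trimmed, nothing else is normalised.
#'
#' @param source_id Single string labelling the annotation source.
#' @param term_to_genes Named list; each component is a character vector of
#'   gene ids annotated to that term. Names are term ids, unique within the
#'   space. Duplicated genes within one term are collapsed.
#' @param organism Single string; free-text organism label.
#' @param term_names Optional named character vector of human-readable term
#'   descriptions (names are term ids).
#' @param universe Optional character vector: the organism gene list used as
#'   denominator for per-term fractions and as hypergeometric population.
#'   Defaults to the union of all annotated genes; when supplied it must
#'   contain every annotated gene.
#' @return An object of class `AnnotationSpace`.
#' @examples
#' sp <- annotation_space("GO-BP", list(T1 = c("a", "b"), T2 = c("b", "c")))
#' length(sp$universe) # 3
#' @export
annotation_space <- function(source_id, term_to_genes, organism = "unknown",
                             term_names = NULL, universe = NULL) {
  stopifnot(is.character(source_id), length(source_id) == 1L, nzchar(source_id))
  if (!is.list(term_to_genes) || is.null(names(term_to_genes)) ||
      anyNA(names(term_to_genes)) || any(!nzchar(names(term_to_genes))))
    stop("`term_to_genes` must be a named list of character vectors")
  if (anyDuplicated(names(term_to_genes)))
    stop("term ids must be unique within an annotation space")
  term_to_genes <- lapply(term_to_genes, function(g) {
    g <- trimws(as.character(g))
    unique(g[nzchar(g)])
  })
  annotated <- unique(unlist(term_to_genes, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(annotated)
  } else {
    universe <- unique(trimws(as.character(universe)))
    missing <- setdiff(annotated, universe)
    if (length(missing))
      stop("universe is missing ", length(missing),
           " annotated gene(s), e.g. ", missing[1L])
  }
  if (!is.null(term_names)) {
    term_names <- term_names[intersect(names(term_names), names(term_to_genes))]
  }
  structure(
    list(source_id = source_id, organism = organism,
         term_to_genes = term_to_genes, term_names = term_names,
         universe = universe),
    class = "AnnotationSpace")
}

#' @export
print.AnnotationSpace <- function(x, ...) {
  cat(sprintf("<AnnotationSpace> %s (%s): %d terms, universe of %d genes\n",
              x$source_id, x$organism, length(x$term_to_genes),
              length(x$universe)))
  invisible(x)
}

# term ids carried outside their space are prefixed "SOURCE:termid";
# the split is on the FIRST colon only, so ids like GO:0007165 survive.
prefix_terms <- function(space, terms = names(space$term_to_genes)) {
  paste0(space$source_id, ":", terms)
}

split_term <- function(term) {
  pos <- regexpr(":", term, fixed = TRUE)
  if (any(pos < 0))
    stop("term id(s) without a source prefix: ",
         paste(utils::head(term[pos < 0], 3L), collapse = ", "))
  data.frame(space = substr(term, 1L, pos - 1L),
             term = substr(term, pos + 1L, nchar(term)),
             stringsAsFactors = FALSE)
}

#' Read annotation spaces from a GMT file
#'
#' GMT is tab-separated: set id, description, then one gene per field.
#' Set ids may carry a source prefix before the first colon
#' (`GO-BP:GO:0007165`); lines are grouped into one `AnnotationSpace` per
#' distinct prefix. Unprefixed ids fall back to a single space whose
#' `source_id` is `default_source`.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector (or path to a universe file,
#'   see [read_universe()]) overriding the default universe, which is the
#'   union of all genes in the file, shared by all returned spaces.
#' @param organism Organism label stored on every returned space.
#' @param default_source Source label for unprefixed set ids.
#' @return A named list of `AnnotationSpace` objects, one per source.
#' @export
read_gmt <- function(path, universe = NULL, organism = "unknown",
                     default_source = "GMT") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " in ", path,
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  if (anyDuplicated(ids))
    stop("duplicated set id in ", path, ": ", ids[anyDuplicated(ids)])
  pos <- regexpr(":", ids, fixed = TRUE)
  source <- ifelse(pos > 0, substr(ids, 1L, pos - 1L), default_source)
  term <- ifelse(pos > 0, substr(ids, pos + 1L, nchar(ids)), ids)
  if (is.character(universe) && length(universe) == 1L && file.exists(universe))
    universe <- read_universe(universe)
  if (is.null(universe))
    universe <- sort(unique(trimws(unlist(genes, use.names = FALSE))))
  out <- lapply(unique(source), function(s) {
    sel <- source == s
    annotation_space(
      s, stats::setNames(genes[sel], term[sel]), organism = organism,
      term_names = stats::setNames(descs[sel], term[sel]), universe = universe)
  })
  stats::setNames(out, unique(source))
}

#' Write annotation spaces (or any named gene-set list) to GMT
#'
#' @param x An `AnnotationSpace`, a list of them, or a named list of
#'   character vectors. Spaces write prefixed set ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  as_rows <- function(sp) {
    if (inherits(sp, "AnnotationSpace")) {
      ids <- prefix_terms(sp)
      desc <- if (is.null(sp$term_names)) names(sp$term_to_genes)
              else sp$term_names[names(sp$term_to_genes)]
      desc[is.na(desc)] <- ""
      mapply(function(i, d, g) paste(c(i, d, g), collapse = "\t"),
             ids, desc, sp$term_to_genes, USE.NAMES = FALSE)
    } else {
      mapply(function(i, g) paste(c(i, "", g), collapse = "\t"),
             names(sp), sp, USE.NAMES = FALSE)
    }
  }
  if (inherits(x, "AnnotationSpace")) x <- list(x)
  if (all(vapply(x, inherits, TRUE, "AnnotationSpace"))) {
    rows <- unlist(lapply(x, as_rows), use.names = FALSE)
  } else rows <- as_rows(x)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene universe file
#'
#' One identifier per line, UTF-8; blank lines and `#` comments ignored.
#'
#' @param path Path to the file.
#' @return Character vector of unique gene ids.
#' @export
read_universe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read an annotation space from a two-column gene/term TSV
#'
#' Alternate loader for flat `gene<TAB>term` exports.
#'
#' @inheritParams read_gmt
#' @param source_id Source label for the resulting space.
#' @return A single `AnnotationSpace`.
#' @export
read_gene_term_tsv <- function(path, source_id = "TSV", universe = NULL,
                               organism = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty annotation TSV: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": expected gene<TAB>term")
  gene <- trimws(vapply(fields, `[[`, "", 1L))
  term <- trimws(vapply(fields, `[[`, "", 2L))
  annotation_space(source_id, split(gene, term), organism = organism,
                   universe = universe)
}

#' Per-term gene-count statistics of an annotation space
#'
#' Computes Ng (genes per term), its fraction of the universe, and the mean,
#' standard deviation and quartiles of the Ng distribution — the ingredients
#' of the generic-term outlier rule.
#'
#' @param space An `AnnotationSpace` with at least one term.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list with `per_term` (data.frame: term, ng, fraction),
#'   `mean_ng`, `sigma_ng`, `quartiles` (0/25/50/75/100%), `n_terms`,
#'   `universe_size`.
#' @examples
#' sp <- annotation_space("GO-BP", list(T1 = letters[1:2], T2 = letters[1:4]),
#'                        universe = letters)
#' term_frequency_stats(sp)$per_term
#' @export
term_frequency_stats <- function(space, sd_type = c("sample", "population")) {
  stopifnot(inherits(space, "AnnotationSpace"))
  sd_type <- match.arg(sd_type)
  ng <- lengths(space$term_to_genes)
  if (!length(ng)) stop("annotation space has no terms")
  nu <- length(space$universe)
  sig <- if (length(ng) < 2L) 0 else stats::sd(ng)
  if (sd_type == "population")
    sig <- sqrt(mean((ng - mean(ng))^2))
  list(per_term = data.frame(term = names(ng), ng = as.integer(ng),
                             fraction = as.numeric(ng) / nu,
                             row.names = NULL, stringsAsFactors = FALSE),
       mean_ng = mean(ng), sigma_ng = sig,
       quartiles = stats::quantile(ng, c(0, .25, .5, .75, 1)),
       n_terms = length(ng), universe_size = nu)
}

#' Tag generic (promiscuous) terms of an annotation space
#'
#' A term is generic when its gene count exceeds the Z-score threshold
#' `mean + n_factor * sigma` of the space's per-term gene-count
#' distribution (strict inequality). Generic terms are tagged, never
#' removed: downstream they only count when co-occurring with specific
#' terms. The deviation factor defaults to 4.
#'
#' @param space An `AnnotationSpace` with at least two terms.
#' @param n_factor Non-negative deviation factor `n` of the threshold.
#' @param sd_type Passed to [term_frequency_stats()].
#' @return A `GenericTermPolicy`: list with `space_id`, `mean_ng`,
#'   `sigma_ng`, `n_factor`, `generic_terms` (character vector of raw term
#'   ids within the space).
#' @export
detect_generic_terms <- function(space, n_factor = 4,
                                 sd_type = c("sample", "population")) {
  stopifnot(inherits(space, "AnnotationSpace"))
  if (length(space$term_to_genes) < 2L)
    stop("need at least two terms to estimate the outlier threshold")
  if (!is.numeric(n_factor) || length(n_factor) != 1L || n_factor < 0)
    stop("`n_factor` must be a single non-negative number")
  st <- term_frequency_stats(space, sd_type = match.arg(sd_type))
  thr <- st$mean_ng + n_factor * st$sigma_ng
  generic <- st$per_term$term[st$per_term$ng > thr]
  structure(
    list(space_id = space$source_id, mean_ng = st$mean_ng,
         sigma_ng = st$sigma_ng, n_factor = n_factor,
         threshold = thr, generic_terms = sort(generic)),
    class = "GenericTermPolicy")
}

#' @export
print.GenericTermPolicy <- function(x, ...) {
  cat(sprintf(
    "<GenericTermPolicy> %s: Ng > %.4g (mean %.4g + %g*sigma %.4g); %d generic term(s)\n",
    x$space_id, x$threshold, x$mean_ng, x$n_factor, x$sigma_ng,
    length(x$generic_terms)))
  invisible(x)
}

# policies: list of GenericTermPolicy, indexable by space_id.
# Returns logical vector over prefixed terms; errors on unknown spaces.
is_generic_term <- function(terms, policies) {
  if (inherits(policies, "GenericTermPolicy")) policies <- list(policies)
  names(policies) <- vapply(policies, `[[`, "", "space_id")
  parts <- split_term(terms)
  unknown <- setdiff(unique(parts$space), names(policies))
  if (length(unknown))
    stop("no generic-term policy for annotation space(s): ",
         paste(unknown, collapse = ", "))
  mapply(function(s, t) t %in% policies[[s]]$generic_terms,
         parts$space, parts$term, USE.NAMES = FALSE)
}
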
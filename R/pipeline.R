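pipeline_defaults <- function() list(
  mode = "mea", min_support = 3L, p_max = 0.05, n_factor = 4,
  depth_fraction = 0.20, step = 0.10, min_elements = 2L,
  p_weight = "literal", population = "union", out_prefix = NULL,
  json = FALSE)

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json: ", path)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full enrich-filter-link-score pipeline
#'
#' End-to-end orchestration: load annotation spaces and query, generate
#' (or load) GeneTerm-sets, run the four linker steps, and write the
#' metagroup report, the element table and a run log with per-step counts.
#'
#' @param config A list, or a path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{spaces}{GMT path(s), or a list of `AnnotationSpace` objects.}
#'     \item{query}{Path to a one-gene-per-line file, or a character
#'       vector. Required unless `input` is given.}
#'     \item{input}{Optional GeneTerm-set TSV replacing built-in
#'       enrichment (its genes define the query unless `query` is given).}
#'     \item{universe}{Optional universe file or character vector.}
#'     \item{mode}{`"mea"` (default, concurrent) or `"sea"` (singular).}
#'     \item{min_support, p_max, n_factor, depth_fraction, step,
#'       min_elements, p_weight, population}{Tuning knobs; see
#'       [concurrent_enrichment()] and [link_metagroups()].}
#'     \item{out_prefix}{If set, writes `<prefix>_metagroups.tsv`,
#'       `<prefix>_elements.tsv`, `<prefix>_log.txt` (and
#'       `<prefix>_metagroups.json` when `json: true`).}
#'   }
#' @return Invisibly, a list with `metagroups`, `elements`, `counts`,
#'   `query` and the paths written (`files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)

  spaces <- pipeline_stage("load_spaces", {
    if (is.null(cfg$spaces)) stop("no annotation spaces configured")
    if (is.character(cfg$spaces)) {
      sp <- unlist(lapply(cfg$spaces, read_gmt), recursive = FALSE)
      as_space_list(sp)
    } else as_space_list(cfg$spaces)
  })
  if (!is.null(cfg$universe)) {
    uni <- if (is.character(cfg$universe) && length(cfg$universe) == 1L &&
               file.exists(cfg$universe)) read_universe(cfg$universe)
           else as.character(cfg$universe)
    spaces <- lapply(spaces, function(sp)
      annotation_space(sp$source_id, sp$term_to_genes, sp$organism,
                       sp$term_names, universe = uni))
  }
  universe <- sort(unique(unlist(lapply(spaces, `[[`, "universe"),
                                 use.names = FALSE)))

  elements_in <- NULL
  if (!is.null(cfg$input))
    elements_in <- pipeline_stage("load_genetermsets",
                                  read_genetermsets(cfg$input, spaces))

  query_genes <- pipeline_stage("load_query", {
    if (!is.null(cfg$query)) {
      if (is.character(cfg$query) && length(cfg$query) == 1L &&
          file.exists(cfg$query)) read_universe(cfg$query)
      else as.character(cfg$query)
    } else if (!is.null(elements_in)) {
      sort(unique(unlist(lapply(elements_in, `[[`, "genes"))))
    } else stop("empty query: configure `query` or `input`")
  })
  if (!length(query_genes)) pipeline_stage("load_query", stop("empty query"))
  query <- pipeline_stage("query_context",
                          query_context(query_genes, length(universe)))

  if (is.null(elements_in)) {
    enrich <- if (identical(cfg$mode, "sea")) singular_enrichment
              else concurrent_enrichment
    elements_in <- pipeline_stage("enrichment",
      enrich(query, spaces, min_support = cfg$min_support,
             p_max = cfg$p_max))
  }

  res <- pipeline_stage("linker",
    link_metagroups(elements_in, query, spaces, n_factor = cfg$n_factor,
                    depth_fraction = cfg$depth_fraction, step = cfg$step,
                    min_elements = cfg$min_elements,
                    p_weight_mode = cfg$p_weight,
                    population = cfg$population))

  files <- character(0)
  log_lines <- c(
    sprintf("query_genes\t%d", query$M),
    sprintf("universe_size\t%d", query$universe_size),
    sprintf("%s\t%d", names(res$counts), unlist(res$counts)))
  if (!is.null(cfg$out_prefix)) {
    files <- pipeline_stage("report", {
      mg <- paste0(cfg$out_prefix, "_metagroups.tsv")
      el <- paste0(cfg$out_prefix, "_elements.tsv")
      lg <- paste0(cfg$out_prefix, "_log.txt")
      write_metagroup_report(res$metagroups, mg)
      write_element_report(res$metagroups, el)
      con <- file(lg, open = "wb"); writeLines(log_lines, con,
                                               useBytes = TRUE); close(con)
      out <- c(metagroups = mg, elements = el, log = lg)
      if (isTRUE(cfg$json)) {
        js <- paste0(cfg$out_prefix, "_metagroups.json")
        jsonlite::write_json(metagroup_table(res$metagroups), js,
                             dataframe = "rows", digits = NA, pretty = TRUE)
        out <- c(out, json = js)
      }
      out
    })
  }
  message(paste(log_lines, collapse = "; "))
  invisible(list(metagroups = res$metagroups, elements = res$elements,
                 counts = res$counts, query = query, files = files))
}
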
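# Readers and writers for the pipeline's file formats. All tables are
# UTF-8 CSV with a header row; set-valued fields are pipe-delimited.
# Writers may prepend run-metadata comment lines ("#"), which every
# reader skips. Comments never carry timestamps so reruns with the same
# configuration and seed are byte-identical.

#' Write a data frame as CSV with optional comment header
#'
#' @param df data.frame.
#' @param path output file.
#' @param comments character vector of metadata lines (written with a
#'   leading `"# "`).
#' @export
write_csv_c <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_c()]
#'
#' @param path input file.
#' @return data.frame (comment lines skipped).
#' @export
read_csv_c <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           check.names = FALSE, encoding = "UTF-8")
}

#' Write prescriptions to CSV
#'
#' @param prescriptions prescription table.
#' @param path output file.
#' @param format `"wide"` (one row per prescription, pipe-delimited
#'   `herbs`) or `"long"` (one row per herb).
#' @param comments metadata comment lines.
#' @export
write_prescriptions <- function(prescriptions, path,
                                format = c("wide", "long"),
                                comments = character()) {
  format <- match.arg(format)
  if (format == "wide") {
    keep <- intersect(c("prescription_id", "patient_id", "herbs", "dose"),
                      names(prescriptions))
    write_csv_c(prescriptions[, keep, drop = FALSE], path, comments)
  } else {
    items <- herb_list(prescriptions)
    long <- data.frame(
      prescription_id = rep(prescriptions$prescription_id, lengths(items)),
      patient_id = rep(prescriptions$patient_id, lengths(items)),
      herb = unlist(items), stringsAsFactors = FALSE)
    if (!is.null(prescriptions$dose)) {
      long$dose <- as.numeric(unlist(strsplit(prescriptions$dose, "|",
                                              fixed = TRUE)))
    }
    write_csv_c(long, path, comments)
  }
  invisible(path)
}

#' Read prescriptions from CSV
#'
#' Accepts either the wide layout (pipe-delimited `herbs` field) or the
#' long layout (`prescription_id`, `herb` per row), which is detected
#' from the header.
#'
#' @param path input file.
#' @return wide-format prescription table.
#' @export
read_prescriptions <- function(path) {
  df <- read_csv_c(path)
  if ("herbs" %in% names(df)) {
    if (any(df$herbs == "" | is.na(df$herbs))) {
      stop("malformed prescription file ", path,
           ": empty herbs field", call. = FALSE)
    }
    return(df)
  }
  if (!all(c("prescription_id", "herb") %in% names(df))) {
    stop("malformed prescription file ", path, ": need a 'herbs' column ",
         "(wide) or 'prescription_id' + 'herb' columns (long)",
         call. = FALSE)
  }
  sp <- split(df, df$prescription_id)
  out <- data.frame(
    prescription_id = names(sp),
    patient_id = vapply(sp, function(d) {
      as.character(d$patient_id[1] %||% NA_character_)
    }, ""),
    herbs = vapply(sp, function(d) paste(d$herb, collapse = "|"), ""),
    stringsAsFactors = FALSE)
  if ("dose" %in% names(df)) {
    out$dose <- vapply(sp, function(d) paste(d$dose, collapse = "|"), "")
  }
  rownames(out) <- NULL
  out
}

#' Write a pathway collection as GMT
#'
#' Standard tab-separated gene-set format: name, description (the
#' category path), then one member per field.
#'
#' @param collection a `pathway_collection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection$pathways), function(nm) {
    paste(c(nm, collection$categories[nm] %||% "",
            collection$pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a pathway collection from GMT
#'
#' @param path GMT file; the description field is kept as the category
#'   path.
#' @param universe optional explicit universe; defaults to the union of
#'   members.
#' @return a `pathway_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("malformed GMT ", path, ": line ", short[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  pw <- lapply(parts, function(x) x[-(1:2)])
  names(pw) <- vapply(parts, `[[`, "", 1)
  cats <- vapply(parts, `[[`, "", 2)
  cats[cats == ""] <- NA_character_
  names(cats) <- names(pw)
  pathway_collection(pw, cats, universe)
}

#' Export a network as an edge list and GraphML
#'
#' @param network an `igraph` network.
#' @param edge_path tab-separated edge list (source, target, support,
#'   confidence, lift); `NULL` to skip.
#' @param graphml_path GraphML file with node attributes; `NULL` to skip.
#' @param assignment optional `cluster_assignment`; adds `cluster` and
#'   `is_core` node attributes to the GraphML export.
#' @export
write_network <- function(network, edge_path = NULL, graphml_path = NULL,
                          assignment = NULL) {
  if (!is.null(edge_path)) {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("source", "target")
    con <- file(edge_path, open = "wt", encoding = "UTF-8")
    write.table(el, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  if (!is.null(graphml_path)) {
    g <- network
    if (!is.null(assignment)) {
      memb <- assignment$membership[igraph::V(g)$name]
      core <- identify_core(g, assignment)
      g <- igraph::set_vertex_attr(g, "cluster", value = as.integer(memb))
      g <- igraph::set_vertex_attr(
        g, "is_core", value = igraph::V(g)$name %in% core)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON, which YAML subsumes) file with the thresholds, paths
#' and the global seed of a pipeline run; missing fields fall back to
#' package defaults.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' Validate (and complete) a pipeline configuration list
#'
#' @param config named list; see [default_config()] for the fields.
#' @return config with defaults filled in.
#' @export
validate_config <- function(config) {
  def <- default_config()
  for (nm in names(def)) config[[nm]] <- config[[nm]] %||% def[[nm]]
  stopifnot(config$min_support >= 0, config$min_confidence >= 0,
            config$min_lift >= 0, config$top_n >= 1,
            config$ob_min >= 0, config$ob_min <= 1,
            config$dl_min >= 0, config$dl_min <= 1,
            config$alpha > 0, config$alpha <= 1)
  config$ob_units <- match.arg(config$ob_units, c("fraction", "percent"))
  config$cluster_method <- match.arg(config$cluster_method,
                                     c("greedy", "louvain"))
  config$seed <- as.integer(config$seed)
  config
}

#' Default pipeline configuration
#'
#' Mining thresholds default to pair support >= 1 percent, confidence
#' >= 15 percent and lift >= 1, permissive enough to retain every
#' network-worthy pair while discarding negatively associated ones; the
#' network keeps the top 100 pairs.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(seed = 42L, n_prescriptions = 20000L,
       min_support = 1, min_confidence = 15, min_lift = 1,
       top_n = 100L, cluster_method = "greedy",
       ob_min = 0.30, dl_min = 0.18, ob_units = "fraction",
       alpha = 0.05, correction = "BH")
}
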
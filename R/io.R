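## On-disk formats: PoolGraph as GraphML (xml2) or a documented JSON
## dialect (jsonlite); event logs as JSON-lines; run manifests.
## Floating-point vertex parameters are serialized with 17 significant
## digits so that read(write(x)) is bit-exact.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a pool graph to GraphML or JSON
#'
#' GraphML stores the discrete label as vertex attribute `"label"` and
#' each numeric parameter as a (possibly vector-valued, comma-separated)
#' attribute; undirected graphs are serialized with one edge per
#' symmetric pair. The JSON dialect has fields `directed`, `vertices`
#' (list of `{id, label, params}`) and `edges` (list of `[from, to]`).
#'
#' @param state a [PoolGraph-class].
#' @param path output path.
#' @param format `"graphml"` or `"json"` (default: by file extension).
#' @export
writeState <- function(state, path,
                       format = c("auto", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path)) "graphml" else "json"
  idx <- which(state@active)
  verts <- lapply(idx, function(i) {
    ## numeric parameters are encoded as 17-significant-digit strings so
    ## that both on-disk formats round-trip doubles bit-exactly
    list(id = i - 1L, label = state@label[i],
         params = lapply(state@params[[i]],
                         function(v) paste(fmtNum(unname(v)),
                                           collapse = ",")))
  })
  e <- which(state@adj == 1L, arr.ind = TRUE)
  if (!state@directed && nrow(e)) e <- e[e[, 1] < e[, 2], , drop = FALSE]
  edges <- lapply(seq_len(nrow(e)), function(r)
    c(e[r, 1] - 1L, e[r, 2] - 1L))
  if (format == "json") {
    obj <- list(directed = state@directed,
                vertices = verts,
                edges = edges)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  ## GraphML
  paramNames <- unique(unlist(lapply(verts, function(v) names(v$params))))
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "label", `for` = "node",
                      attr.name = "label", attr.type = "string")
  for (pn in paramNames)
    xml2::xml_add_child(doc, "key", id = pn, `for` = "node",
                        attr.name = pn, attr.type = "string")
  gr <- xml2::xml_add_child(doc, "graph", id = "G",
                            edgedefault = if (state@directed) "directed"
                                          else "undirected")
  for (v in verts) {
    nd <- xml2::xml_add_child(gr, "node", id = paste0("n", v$id))
    d <- xml2::xml_add_child(nd, "data", key = "label")
    xml2::xml_text(d) <- v$label
    for (pn in names(v$params)) {
      d <- xml2::xml_add_child(nd, "data", key = pn)
      xml2::xml_text(d) <- v$params[[pn]]
    }
  }
  for (e2 in edges)
    xml2::xml_add_child(gr, "edge", source = paste0("n", e2[1]),
                        target = paste0("n", e2[2]))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a pool graph from GraphML or JSON
#'
#' @param path input path; @param format as in [writeState()].
#' @return a [PoolGraph-class].
#' @export
readState <- function(path, format = c("auto", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path)) "graphml" else "json"
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    ids <- vapply(obj$vertices, function(v) v$id, numeric(1))
    n <- max(c(ids + 1, 1))
    g <- poolGraph(capacity = n, directed = isTRUE(obj$directed))
    lab <- rep(NA_character_, n)
    pars <- rep(list(list()), n)
    for (v in obj$vertices) {
      lab[v$id + 1] <- v$label
      pars[[v$id + 1]] <- lapply(v$params, function(p)
        as.numeric(strsplit(p, ",", fixed = TRUE)[[1]]))
    }
    adj <- matrix(0L, n, n)
    for (e in obj$edges) {
      adj[e[[1]] + 1, e[[2]] + 1] <- 1L
      if (!isTRUE(obj$directed)) adj[e[[2]] + 1, e[[1]] + 1] <- 1L
    }
    return(poolGraphFromConfig(lab, adj, directed = isTRUE(obj$directed),
                               params = pars))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  gr <- xml2::xml_find_first(doc, ".//graph")
  directed <- identical(xml2::xml_attr(gr, "edgedefault"), "directed")
  nodes <- xml2::xml_find_all(gr, ".//node")
  if (!length(nodes)) stop("schema error: GraphML has no nodes")
  ids <- as.integer(sub("^n", "", xml2::xml_attr(nodes, "id")))
  n <- max(ids) + 1L
  lab <- rep(NA_character_, n)
  pars <- rep(list(list()), n)
  for (ni in seq_along(nodes)) {
    i <- ids[ni] + 1L
    data <- xml2::xml_find_all(nodes[[ni]], "./data")
    keys <- xml2::xml_attr(data, "key")
    if (!"label" %in% keys)
      stop("schema error at node ", ids[ni], ": missing 'label' attribute")
    for (di in seq_along(data)) {
      key <- keys[di]; val <- xml2::xml_text(data[[di]])
      if (key == "label") lab[i] <- val
      else pars[[i]][[key]] <-
          as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  adj <- matrix(0L, n, n)
  for (ed in xml2::xml_find_all(gr, ".//edge")) {
    s <- as.integer(sub("^n", "", xml2::xml_attr(ed, "source"))) + 1L
    t <- as.integer(sub("^n", "", xml2::xml_attr(ed, "target"))) + 1L
    adj[s, t] <- 1L
    if (!directed) adj[t, s] <- 1L
  }
  poolGraphFromConfig(lab, adj, directed = directed, params = pars)
}

#' Write an event log as JSON-lines
#' @param log an [EventLog-class]; @param path output path.
#' @export
writeEventLog <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (e in log@events)
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read a JSON-lines event log
#' @param path input path.
#' @export
readEventLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  new("EventLog", events = lapply(lines[nzchar(lines)], function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE)))
}

#' Write a reproducibility manifest for a run
#'
#' Records the ruleset (hashed and verbatim), seed, configuration and
#' package version -- sufficient to reproduce the run byte-identically.
#'
#' @param path output path; @param rs ruleset; @param seed seed;
#' @param config named list of run settings.
#' @export
writeManifest <- function(path, rs, seed, config = list()) {
  txt <- formatRuleset(rs)
  manifest <- list(
    package = "dggsim",
    version = as.character(utils::packageVersion("dggsim")),
    seed = seed,
    rulesetHash = sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 997)),
    ruleset = txt,
    config = config,
    rng = "Mersenne-Twister")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
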
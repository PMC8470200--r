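# A minimal in-memory triple store with deterministic Turtle and JSON-LD
# serialization, plus a parser for the package's own output (used for
# round-trip checks). Nodes are stored as CURIEs under the declared prefixes;
# literals carry an xsd datatype tag.

#' Default namespace table
#'
#' Prefix map used throughout the knowledge graph: `sosa` (observations),
#' `dul` (DOLCE+DnS Ultralite), `oa` (Web Annotation vocabulary), `sh`
#' (SHACL), plus the two project namespaces `em` (domain extensions: problem
#' types, linking properties) and `ms` (monitored-subject instances: problems,
#' views, observations).
#'
#' @return Named character vector mapping prefix to IRI.
#' @export
wkg_namespaces <- function() {
  c(rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    xsd  = "http://www.w3.org/2001/XMLSchema#",
    sosa = "http://www.w3.org/ns/sosa/",
    dul  = "http://www.ontologydesignpatterns.org/ont/dul/DUL.owl#",
    oa   = "http://www.w3.org/ns/oa#",
    sh   = "http://www.w3.org/ns/shacl#",
    em   = "https://w3id.org/wearkg/em#",
    ms   = "https://w3id.org/wearkg/ms#")
}

empty_triples <- function() {
  data.frame(s = character(), p = character(), o = character(),
             lit = logical(), dt = character(), stringsAsFactors = FALSE)
}

#' Create an empty knowledge graph
#'
#' @param namespaces Named character vector of prefix -> IRI; defaults to
#'   [wkg_namespaces()].
#' @return An object of class `kg` holding a (deduplicated) triple table.
#' @export
kg_new <- function(namespaces = wkg_namespaces()) {
  structure(list(triples = empty_triples(), namespaces = namespaces),
            class = "kg")
}

#' Add triples to a knowledge graph
#'
#' Vectorized over `s`, `p`, `o`. Adding a triple that is already present is
#' a no-op (set semantics), so `kg_add` is idempotent.
#'
#' @param kg A `kg`.
#' @param s,p,o Subject / predicate / object CURIEs (or literal lexical forms
#'   when `lit` is `TRUE`).
#' @param lit Logical (recycled): is `o` a literal?
#' @param dt Literal datatype tag (`"string"`, `"integer"`, `"decimal"`,
#'   `"dateTime"`); ignored for IRI objects.
#' @return The enlarged `kg`.
#' @export
kg_add <- function(kg, s, p, o, lit = FALSE, dt = "string") {
  stopifnot(inherits(kg, "kg"))
  n <- max(length(s), length(p), length(o))
  add <- data.frame(s = rep_len(as.character(s), n),
                    p = rep_len(as.character(p), n),
                    o = rep_len(as.character(o), n),
                    lit = rep_len(lit, n),
                    dt = rep_len(ifelse(rep_len(lit, n), dt, NA_character_), n),
                    stringsAsFactors = FALSE)
  all <- rbind(kg$triples, add)
  kg$triples <- all[!duplicated(all[c("s", "p", "o", "lit")]), , drop = FALSE]
  rownames(kg$triples) <- NULL
  kg
}

#' Number of distinct triples in a graph
#' @param kg A `kg`.
#' @return Integer count.
#' @export
kg_size <- function(kg) nrow(kg$triples)

# Filtered view of the triple table; NULL matches anything.
kg_match <- function(kg, s = NULL, p = NULL, o = NULL) {
  t <- kg$triples
  keep <- rep(TRUE, nrow(t))
  if (!is.null(s)) keep <- keep & t$s %in% s
  if (!is.null(p)) keep <- keep & t$p %in% p
  if (!is.null(o)) keep <- keep & t$o %in% o
  t[keep, , drop = FALSE]
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg> %d triples, %d namespaces\n",
              kg_size(x), length(x$namespaces)))
  invisible(x)
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

ttl_object <- function(o, lit, dt) {
  ifelse(!lit, o,
         ifelse(dt == "string",
                paste0("\"", ttl_escape(o), "\""),
                paste0("\"", ttl_escape(o), "\"^^xsd:", dt)))
}

#' Serialize a knowledge graph
#'
#' Output is deterministic: triples are emitted in lexicographic
#' (subject, predicate, object) order, so identical graphs serialize to
#' byte-identical documents.
#'
#' @param kg A `kg`.
#' @param format `"turtle"` or `"json-ld"`.
#' @return A single character string holding the document.
#' @export
serialize_graph <- function(kg, format = c("turtle", "json-ld")) {
  stopifnot(inherits(kg, "kg"))
  format <- match.arg(format)
  t <- kg$triples
  t <- t[order(t$s, t$p, t$o, method = "radix"), , drop = FALSE]
  if (format == "turtle") {
    header <- sprintf("@prefix %s: <%s> .", names(kg$namespaces), kg$namespaces)
    body <- if (nrow(t)) {
      sprintf("%s %s %s .", t$s, t$p, ttl_object(t$o, t$lit, t$dt))
    } else character()
    return(paste0(paste(c(header, "", body), collapse = "\n"), "\n"))
  }
  # JSON-LD: one node object per subject, predicates sorted, values as
  # explicit @id / @value maps so parsing is unambiguous.
  by_subj <- split(t, factor(t$s, levels = unique(t$s)))
  graph <- lapply(by_subj, function(rows) {
    node <- list(`@id` = rows$s[1])
    by_pred <- split(rows, factor(rows$p, levels = unique(rows$p)))
    for (pr in by_pred) {
      vals <- lapply(seq_len(nrow(pr)), function(i) {
        if (pr$lit[i]) {
          v <- list(`@value` = pr$o[i])
          if (pr$dt[i] != "string") v$`@type` <- paste0("xsd:", pr$dt[i])
          v
        } else list(`@id` = pr$o[i])
      })
      node[[pr$p[1]]] <- vals
    }
    node
  })
  names(graph) <- NULL
  jsonlite::toJSON(list(`@context` = as.list(kg$namespaces), `@graph` = graph),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Parse a document produced by [serialize_graph()]
#'
#' Supports the subset of Turtle / JSON-LD that the serializer emits
#' (prefixed names, typed literals, one triple per line). Intended for
#' round-trip verification, not as a general RDF parser.
#'
#' @param text Document text.
#' @param format `"turtle"` or `"json-ld"`.
#' @return A `kg`.
#' @export
parse_graph <- function(text, format = c("turtle", "json-ld")) {
  format <- match.arg(format)
  if (format == "json-ld") return(parse_jsonld(text))
  parse_turtle(text)
}

parse_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pre <- grepl("^@prefix ", lines)
  ns <- c()
  for (l in lines[pre]) {
    m <- regmatches(l, regexec("^@prefix ([A-Za-z][A-Za-z0-9_]*): <([^>]*)> \\.$", l))[[1]]
    wkg_stopifnot(length(m) == 3L, paste0("bad @prefix line: ", l))
    ns[m[2]] <- m[3]
  }
  kg <- kg_new(ns)
  trip_re <- paste0(
    "^(\\S+) (\\S+) ",
    "(?:\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^xsd:([A-Za-z]+))?|(\\S+))",
    " \\.$")
  body <- lines[!pre]
  if (!length(body)) return(kg)
  m <- regmatches(body, regexec(trip_re, body))
  bad <- vapply(m, length, 0L) == 0L
  wkg_stopifnot(!any(bad),
                paste0("unparseable triple: ", body[which(bad)[1]]))
  s <- vapply(m, `[`, "", 2L)
  p <- vapply(m, `[`, "", 3L)
  quoted <- vapply(m, function(x) x[6] == "", TRUE)
  o <- ifelse(quoted, ttl_unescape(vapply(m, `[`, "", 4L)),
              vapply(m, `[`, "", 6L))
  dtraw <- vapply(m, `[`, "", 5L)
  dt <- ifelse(quoted, ifelse(dtraw == "", "string", dtraw), NA_character_)
  kg_add(kg, s, p, o, lit = quoted, dt = dt)
}

parse_jsonld <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ns <- unlist(doc$`@context`)
  chunks <- list()
  for (node in doc$`@graph`) {
    for (pred in setdiff(names(node), "@id")) {
      vals <- node[[pred]]
      is_iri <- vapply(vals, function(v) !is.null(v$`@id`), TRUE)
      o <- vapply(vals, function(v) {
        if (is.null(v$`@id`)) as.character(v$`@value`) else v$`@id`
      }, "")
      dt <- vapply(vals, function(v) {
        if (!is.null(v$`@id`)) NA_character_
        else if (is.null(v$`@type`)) "string"
        else sub("^xsd:", "", v$`@type`)
      }, "")
      chunks[[length(chunks) + 1L]] <-
        list(s = rep(node$`@id`, length(o)), p = rep(pred, length(o)),
             o = o, lit = !is_iri, dt = dt)
    }
  }
  kg <- kg_new(ns)
  if (length(chunks)) {
    grab <- function(f) unlist(lapply(chunks, `[[`, f), use.names = FALSE)
    kg$triples <- data.frame(s = grab("s"), p = grab("p"), o = grab("o"),
                             lit = grab("lit"), dt = grab("dt"),
                             stringsAsFactors = FALSE)
  }
  kg
}

# Canonical key set for triple-set equality (ignores row order).
kg_triple_keys <- function(kg) {
  t <- kg$triples
  sort(paste(t$s, t$p, ifelse(t$lit, paste0('"', t$o, '"@', t$dt), t$o)))
}

#' Test two graphs for triple-set equality
#' @param a,b `kg` objects.
#' @return Logical.
#' @export
kg_equal <- function(a, b) identical(kg_triple_keys(a), kg_triple_keys(b))
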
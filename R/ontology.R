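#' Parse an OBO 1.2 flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas and builds the subclass (is_a) DAG used throughout
#' the package. Only `id`, `name`, `namespace`, `is_a`, `alt_id` and
#' `is_obsolete` lines are interpreted; other relationship types (`part_of`,
#' `regulates`, ...) are parsed but ignored, since only subclass transitivity
#' is used for annotation propagation. GO namespaces are normalised to the
#' branch tags `BP`, `MF`, `CC`; any other namespace string is kept as-is.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology_dag`: a list with elements `terms`
#'   (character vector), `name` and `namespace` (named character vectors),
#'   `parents` (named list of direct is_a superclasses), `obsolete`
#'   (character vector) and `alt` (named character vector mapping alternate
#'   ids to their canonical term).
#' @details Obsolete terms keep no outgoing is_a edges (they are never used in
#'   propagation). A dangling `is_a` target or a cyclic is_a graph is an
#'   error; the cycle is reported.
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  # stanza boundaries: a header is a line like [Term] / [Typedef]
  hdr <- grep("^\\[[A-Za-z]+\\]$", lines)
  term_hdr <- which(lines == "[Term]")

  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list(); obsolete <- character(0)
  alt_from <- character(0); alt_to <- character(0)

  for (h in term_hdr) {
    nxt <- hdr[hdr > h]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[seq(h + 1L, length.out = max(0L, end - h))]
    block <- block[nzchar(block)]
    kv <- regmatches(block, regexpr("^[a-z_]+:", block))
    keys <- sub(":$", "", kv)
    vals <- sub("^[a-z_]+:\\s*", "", block)
    vals <- sub("\\s*!.*$", "", vals)  # strip trailing OBO comments

    id <- vals[keys == "id"][1]
    if (is.na(id) || !nzchar(id)) stop("OBO [Term] stanza without an id line")
    obs <- any(keys == "is_obsolete" & tolower(vals) == "true")
    isa <- vals[keys == "is_a"]
    ids <- c(ids, id)
    nm <- vals[keys == "name"][1]
    nms <- c(nms, if (is.na(nm)) "" else nm)
    ns <- vals[keys == "namespace"][1]
    nss <- c(nss, if (is.na(ns)) "" else ns)
    parents[[id]] <- if (obs) character(0) else unique(isa)
    if (obs) obsolete <- c(obsolete, id)
    av <- vals[keys == "alt_id"]
    if (length(av)) { alt_from <- c(alt_from, av); alt_to <- c(alt_to, rep(id, length(av))) }
  }

  if (anyDuplicated(ids)) stop("duplicate term id(s) in OBO input: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(nms) <- ids
  mapped <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")[nss]
  nss <- ifelse(is.na(mapped), nss, mapped)
  names(nss) <- ids
  alt <- alt_to; names(alt) <- alt_from

  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) stop("is_a reference(s) to unknown term(s): ",
                             paste(dangling, collapse = ", "))

  dag <- structure(list(terms = ids, name = nms, namespace = nss,
                        parents = parents, obsolete = obsolete, alt = alt),
                   class = "ontology_dag")
  cyc <- .find_cycle(dag)
  if (length(cyc)) stop("cyclic is_a graph involving: ", paste(cyc, collapse = " -> "))
  dag
}

# Kahn-style peel; returns terms on a cycle (empty if acyclic)
.find_cycle <- function(dag) {
  deg <- vapply(dag$parents, length, 1L)[dag$terms]
  names(deg) <- dag$terms
  children <- .children_map(dag)
  queue <- dag$terms[deg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(dag$terms)) character(0) else names(deg)[deg > 0L]
}

.children_map <- function(dag) {
  ch <- rep(list(character(0)), length(dag$terms)); names(ch) <- dag$terms
  for (t in dag$terms) for (p in dag$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  ch
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", length(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges, ",
      length(x$obsolete), " obsolete, ",
      length(x$alt), " alt ids\n", sep = "")
  invisible(x)
}

#' Strict ancestors of a term
#'
#' All superclasses reachable from `term` through is_a edges, excluding the
#' term itself.
#'
#' @param dag an `ontology_dag`.
#' @param term a term identifier present in `dag`.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  out <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  sort(unique(out))
}

#' Ancestor sets for every term at once
#'
#' Computed in a single topological pass; used by propagation and term
#' selection where per-term calls would be quadratic.
#'
#' @param dag an `ontology_dag`.
#' @return Named list: term id -> character vector of strict ancestors.
#' @export
ancestors_all <- function(dag) {
  ord <- .topo_all(dag)  # parents before children
  anc <- rep(list(character(0)), length(dag$terms)); names(anc) <- dag$terms
  for (t in ord) {
    ps <- dag$parents[[t]]
    if (length(ps))
      anc[[t]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

# full-graph topological order, parents before children
.topo_all <- function(dag) {
  deg <- vapply(dag$parents, length, 1L)[dag$terms]
  names(deg) <- dag$terms
  children <- .children_map(dag)
  queue <- sort(dag$terms[deg == 0L])
  out <- character(0)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    out <- c(out, t)
    for (ch in children[[t]]) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(dag$terms)) stop("cycle in is_a graph")
  out
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Replaces each protein's term set by its upward closure under the subclass
#' relation: annotation with a class implies annotation with every ancestor.
#' The operation is idempotent. Annotations to alternate ids are rewritten to
#' their canonical term first.
#'
#' @param dag an `ontology_dag`.
#' @param ann named list: protein id -> character vector of term ids.
#' @param lenient if `TRUE`, annotations to obsolete or unknown terms are
#'   dropped with a warning instead of raising an error.
#' @return Named list of upward-closed term sets (sorted, unique).
#' @export
propagate_annotations <- function(dag, ann, lenient = FALSE) {
  anc <- ancestors_all(dag)
  bad_unknown <- character(0); bad_obsolete <- character(0)
  out <- lapply(ann, function(ts) {
    ts <- unique(as.character(ts))
    hit <- ts %in% names(dag$alt)
    ts[hit] <- dag$alt[ts[hit]]
    unk <- setdiff(ts, dag$terms)
    obs <- intersect(ts, dag$obsolete)
    if (length(unk)) bad_unknown <<- union(bad_unknown, unk)
    if (length(obs)) bad_obsolete <<- union(bad_obsolete, obs)
    ts <- setdiff(ts, c(unk, obs))
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  if (length(bad_unknown) || length(bad_obsolete)) {
    msg <- paste0(
      if (length(bad_unknown)) paste0("unknown term(s): ", paste(bad_unknown, collapse = ", ")),
      if (length(bad_unknown) && length(bad_obsolete)) "; ",
      if (length(bad_obsolete)) paste0("obsolete term(s): ", paste(bad_obsolete, collapse = ", ")))
    if (lenient) warning("dropped annotations to ", msg) else stop("annotations to ", msg)
  }
  names(out) <- names(ann)
  out
}

#' Select the trained term subset of one ontology branch
#'
#' Ranks the branch's terms by descending annotation count (over the already
#' propagated annotation set), truncates to the `top_k` most annotated, and
#' keeps those meeting `min_count`. Count ties are broken by ascending
#' lexicographic term id so the selection is reproducible.
#'
#' @param dag an `ontology_dag`.
#' @param ann propagated annotations (named list protein -> terms).
#' @param branch branch tag to select from (matched against `dag$namespace`),
#'   e.g. `"BP"`, `"MF"`, `"CC"`.
#' @param top_k maximum number of terms to keep.
#' @param min_count minimum number of annotated proteins per kept term.
#' @return An object of class `term_set`: list with `terms` (rank order),
#'   `index` (named 0-based output positions), `leaves`, `internal` (leaf =
#'   no selected strict descendant, computed w.r.t. the selected subset
#'   only), `branch` and `counts`.
#' @export
select_terms <- function(dag, ann, branch, top_k, min_count = 1L) {
  if (top_k <= 0) stop("top_k must be positive")
  in_branch <- dag$terms[dag$namespace[dag$terms] == branch]
  if (!length(in_branch)) stop("no terms in branch ", branch)
  cnt <- table(factor(unlist(ann, use.names = FALSE), levels = in_branch))
  cnt <- as.integer(cnt); names(cnt) <- in_branch
  ord <- order(-cnt, names(cnt))
  ranked <- names(cnt)[ord]
  kept <- ranked[seq_len(min(top_k, length(ranked)))]
  kept <- kept[cnt[kept] >= min_count]
  if (!length(kept)) stop("no term meets min_count = ", min_count)
  term_set(dag, kept, branch = branch, counts = cnt[kept])
}

#' Construct a term set from an explicit ordered term list
#'
#' @param dag an `ontology_dag`.
#' @param terms ordered character vector of selected term ids.
#' @param branch optional branch tag recorded on the object.
#' @param counts optional named annotation counts.
#' @return A `term_set` (see [select_terms()]).
#' @export
term_set <- function(dag, terms, branch = NA_character_, counts = NULL) {
  if (anyDuplicated(terms)) stop("duplicated terms in term set")
  missing <- setdiff(terms, dag$terms)
  if (length(missing)) stop("terms absent from ontology: ", paste(missing, collapse = ", "))
  anc <- ancestors_all(dag)
  internal <- character(0)
  for (t in terms) internal <- union(internal, intersect(anc[[t]], terms))
  idx <- seq_along(terms) - 1L; names(idx) <- terms
  structure(list(terms = terms, index = idx,
                 leaves = setdiff(terms, internal), internal = internal,
                 branch = branch, counts = counts),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", length(x$terms), " terms (",
      length(x$leaves), " leaves, ", length(x$internal), " internal), branch ",
      x$branch, "\n", sep = "")
  invisible(x)
}

#' Children-before-parents order over a selected term subset
#'
#' Orders the selected terms so that every term appears after all of its
#' selected strict descendants; this is the evaluation order of the recursive
#' max-merge. Ties are broken lexicographically.
#'
#' @param dag an `ontology_dag`.
#' @param terms a `term_set` or character vector of selected terms.
#' @return Character vector: the selected terms in children-first order.
#' @export
topological_order <- function(dag, terms) {
  sel <- if (inherits(terms, "term_set")) terms$terms else terms
  anc <- ancestors_all(dag)
  # selected strict descendants per selected term
  desc <- rep(list(character(0)), length(sel)); names(desc) <- sel
  for (d in sel) for (a in intersect(anc[[d]], sel)) desc[[a]] <- c(desc[[a]], d)
  emitted <- character(0)
  out <- character(0)
  remaining <- sort(sel)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(t) all(desc[[t]] %in% emitted), TRUE)]
    if (!length(ready)) stop("cycle in the induced subclass subgraph")
    out <- c(out, ready)
    emitted <- c(emitted, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

#' Selected-descendant closures per selected term
#'
#' For each selected term, the set of selected terms in its descendant
#' closure, including itself. The max-merge score of a term is the maximum of
#' the raw classifier scores over exactly this set.
#'
#' @inheritParams topological_order
#' @return Named list: selected term -> character vector (self included).
#' @export
descendant_closure <- function(dag, terms) {
  sel <- if (inherits(terms, "term_set")) terms$terms else terms
  anc <- ancestors_all(dag)
  cl <- as.list(sel); names(cl) <- sel
  for (d in sel) for (a in intersect(anc[[d]], sel)) cl[[a]] <- c(cl[[a]], d)
  cl
}

#' Minimal selected strict ancestors (induced direct parents)
#'
#' Direct parents of each selected term within the subgraph induced on the
#' selected subset: the minimal elements of its selected strict ancestors.
#' Used by the cascade wiring of the classifier.
#'
#' @inheritParams topological_order
#' @return Named list: selected term -> character vector of induced parents.
#' @export
induced_parents <- function(dag, terms) {
  sel <- if (inherits(terms, "term_set")) terms$terms else terms
  anc <- ancestors_all(dag)
  lapply(stats::setNames(sel, sel), function(t) {
    sa <- intersect(anc[[t]], sel)
    if (!length(sa)) return(character(0))
    # a is minimal if no other selected ancestor of t has a as ancestor
    keep <- vapply(sa, function(a) !any(vapply(setdiff(sa, a),
                                               function(b) a %in% anc[[b]], TRUE)), TRUE)
    sort(sa[keep])
  })
}

#' Write a toy ontology back out as OBO 1.2 text
#'
#' @param dag an `ontology_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    if (nzchar(dag$name[[t]])) writeLines(paste0("name: ", dag$name[[t]]), con)
    ns <- dag$namespace[[t]]
    ns_out <- c(BP = "biological_process", MF = "molecular_function",
                CC = "cellular_component")[ns]
    writeLines(paste0("namespace: ", if (is.na(ns_out)) ns else ns_out), con)
    for (a in names(dag$alt)[dag$alt == t]) writeLines(paste0("alt_id: ", a), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
    if (t %in% dag$obsolete) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}
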
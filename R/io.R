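## Instance readers/writers.
##
## Two input forms are supported:
##  * the host/parasite Nexus dialect used by Jane and CoRe-PA:
##      BEGIN HOST; TREE ... = <newick> END;
##      BEGIN PARASITE; TREE ... = <newick> END;
##      BEGIN DISTRIBUTION; RANGE p1:h1, p2:h2, ...; END;
##  * a pair of Newick files plus a two-column tab-separated table
##    (parasite leaf TAB host leaf, no header).
## No installed R package reads the host/parasite dialect, so the block
## scanner here is hand-written; the embedded trees still go through the
## Newick path.

#' Read a host--parasite reconciliation instance
#'
#' @param path Path to a Nexus file in the host/parasite dialect
#'   (`format = "nexus"`).
#' @param format `"nexus"` or `"newick-pair"`.
#' @param host,parasite,mapping For `format = "newick-pair"`: paths to
#'   the host Newick file, the parasite Newick file and the tab-separated
#'   leaf association.
#' @return A list with components `host`, `parasite` (both
#'   \code{phylo_tree}) and `phi`, an integer vector over parasite
#'   vertices giving the associated host leaf id for each parasite leaf
#'   (NA for internal vertices).
#' @export
read_instance <- function(path = NULL, format = c("nexus", "newick-pair"),
                          host = NULL, parasite = NULL, mapping = NULL) {
  format <- match.arg(format)
  if (format == "nexus") {
    if (is.null(path)) stop("'path' is required for nexus input")
    parsed <- read_nexus_hp(path)
    make_instance(parsed$host, parsed$parasite, parsed$assoc)
  } else {
    if (is.null(host) || is.null(parasite) || is.null(mapping))
      stop("'host', 'parasite' and 'mapping' paths are required")
    h <- parse_newick(paste(readLines(host, warn = FALSE), collapse = ""))
    p <- parse_newick(paste(readLines(parasite, warn = FALSE),
                            collapse = ""))
    tab <- utils::read.table(mapping, sep = "\t", header = FALSE,
                             colClasses = "character",
                             col.names = c("parasite", "host"),
                             fileEncoding = "UTF-8")
    make_instance(h, p, stats::setNames(tab$host, tab$parasite))
  }
}

## assoc: named character vector parasite-leaf-label -> host-leaf-label
make_instance <- function(h, p, assoc) {
  pleaves <- p$label[p$leaves]
  missing <- setdiff(pleaves, names(assoc))
  if (length(missing))
    stop("incomplete leaf mapping: parasite leaf '", missing[1],
         "' has no host", if (length(missing) > 1)
           paste0(" (", length(missing), " in total)"))
  unknown_p <- setdiff(names(assoc), pleaves)
  if (length(unknown_p))
    stop("mapping references unknown parasite leaf '", unknown_p[1], "'")
  phi <- rep(NA_integer_, p$n)
  phi[p$leaves] <- leaf_id(h, unname(assoc[pleaves]))
  list(host = h, parasite = p, phi = phi)
}

read_nexus_hp <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ## strip nexus comments
  txt <- gsub("\\[[^]]*\\]", "", txt)
  blocks <- extract_blocks(txt)
  known <- c("host", "parasite", "distribution")
  for (nm in setdiff(names(blocks), known))
    warning("skipping unknown nexus block '", toupper(nm), "'")
  for (nm in c("host", "parasite", "distribution"))
    if (!nm %in% names(blocks))
      stop("nexus file lacks a ", toupper(nm), " block: ", path)
  h <- parse_newick(extract_tree(blocks[["host"]], "HOST"))
  p <- parse_newick(extract_tree(blocks[["parasite"]], "PARASITE"))
  rng <- regmatches(blocks[["distribution"]],
                    regexpr("(?is)range\\s+[^;]*;", blocks[["distribution"]],
                            perl = TRUE))
  if (!length(rng)) stop("DISTRIBUTION block has no RANGE statement")
  body <- sub("(?is)^range\\s+", "", sub(";$", "", rng), perl = TRUE)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s*:\\s*")
  bad <- which(lengths(pairs) != 2L)
  if (length(bad)) stop("malformed RANGE entry: '",
                        paste(pairs[[bad[1]]], collapse = ":"), "'")
  assoc <- stats::setNames(vapply(pairs, `[`, "", 2L),
                           vapply(pairs, `[`, "", 1L))
  list(host = h, parasite = p, assoc = assoc)
}

extract_blocks <- function(txt) {
  m <- gregexpr("(?is)begin\\s+(\\w+)\\s*;(.*?)\\bend\\s*;", txt,
                perl = TRUE)[[1]]
  starts <- as.integer(m)
  if (starts[1] == -1L) stop("no nexus blocks found")
  lens <- attr(m, "match.length")
  blocks <- list()
  for (i in seq_along(starts)) {
    chunk <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    name <- tolower(sub("(?is)^begin\\s+(\\w+).*", "\\1", chunk,
                        perl = TRUE))
    body <- sub("(?is)^begin\\s+\\w+\\s*;", "", chunk, perl = TRUE)
    body <- sub("(?is)\\bend\\s*;$", "", body, perl = TRUE)
    blocks[[name]] <- body
  }
  blocks
}

extract_tree <- function(block, what) {
  m <- regmatches(block, regexpr("(?is)tree\\s+[^=]*=\\s*[^;]+;", block,
                                 perl = TRUE))
  if (!length(m)) stop(what, " block has no TREE statement")
  trimws(sub("(?is)^tree\\s+[^=]*=\\s*", "", m, perl = TRUE))
}

#' Write an instance to disk
#'
#' Serializes a host/parasite/association triple either as one Nexus
#' file in the host--parasite dialect or as two Newick files plus a TSV
#' mapping, so generated instances exercise the same readers as user
#' data.
#'
#' @param instance A list as returned by [read_instance()] or
#'   [random_instance()].
#' @param path Output file (nexus) or a directory (newick-pair).
#' @param format `"nexus"` or `"newick-pair"`.
#' @return Invisibly, the paths written.
#' @export
write_instance <- function(instance, path,
                           format = c("nexus", "newick-pair")) {
  format <- match.arg(format)
  h <- instance$host; p <- instance$parasite
  pl <- p$leaves
  assoc <- paste0(p$label[pl], ":", h$label[instance$phi[pl]])
  if (format == "nexus") {
    lines <- c("#NEXUS",
               "BEGIN HOST;",
               paste0("TREE HOST = ", write_newick(h)),
               "END;",
               "BEGIN PARASITE;",
               paste0("TREE PARASITE = ", write_newick(p)),
               "END;",
               "BEGIN DISTRIBUTION;",
               paste0("RANGE ", paste(assoc, collapse = ", "), ";"),
               "END;")
    writeLines(lines, path)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    fh <- file.path(path, "host.nwk")
    fp <- file.path(path, "parasite.nwk")
    fm <- file.path(path, "mapping.tsv")
    writeLines(write_newick(h), fh)
    writeLines(write_newick(p), fp)
    writeLines(paste(p$label[pl], h$label[instance$phi[pl]], sep = "\t"),
               fm)
    invisible(c(host = fh, parasite = fp, mapping = fm))
  }
}

#' Write reconciliations as a text or JSON-lines stream
#'
#' One block per solution: `parasite TAB host TAB event` rows in
#' parasite postorder, a `losses:` line, and the event vector
#' `<c,d,s,l>`.  The JSON-lines variant emits one object per solution
#' with the same fields in a fixed order.
#'
#' @param solutions List of `reconciliation` objects.
#' @param host,parasite The trees the solutions refer to.
#' @param path Output file.
#' @param format `"text"` or `"jsonl"`.
#' @export
write_solutions <- function(solutions, host, parasite, path,
                            format = c("text", "jsonl")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(solutions)) {
    r <- solutions[[i]]
    ev <- ifelse(parasite$is_leaf, "leaf", r$events)
    if (format == "text") {
      writeLines(paste0("# solution ", i), con)
      writeLines(paste(parasite$label, host$label[r$gamma], ev,
                       sep = "\t"), con)
      writeLines(paste0("losses:\t",
                        paste(host$label[r$losses], collapse = ",")), con)
      writeLines(paste0("events:\t<", paste(r$event_vector,
                                            collapse = ","), ">"), con)
      writeLines("", con)
    } else {
      obj <- sprintf(
        '{"solution":%d,"gamma":{%s},"events":{%s},"losses":[%s],"event_vector":[%s],"cost":%s}',
        i,
        paste0('"', parasite$label, '":"', host$label[r$gamma], '"',
               collapse = ","),
        paste0('"', parasite$label[!parasite$is_leaf], '":"',
               r$events[!parasite$is_leaf], '"', collapse = ","),
        paste0('"', host$label[r$losses], '"', collapse = ","),
        paste(r$event_vector, collapse = ","),
        format(r$cost, digits = 15))
      writeLines(obj, con)
    }
  }
  invisible(path)
}
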
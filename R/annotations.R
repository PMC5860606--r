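# Experimental evidence codes: manually verified annotations only.
EXPERIMENTAL_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")

#' Read protein-to-term annotations
#'
#' Accepts either GAF 2.x (17-column gene association format; columns 2, 5
#' and 7 hold the protein id, the GO id and the evidence code) or a plain
#' 3-column TSV `protein<TAB>term<TAB>evidence`. Rows whose evidence code is
#' not in the whitelist are dropped.
#'
#' @param path input file. GAF is auto-detected by a `!gaf-version` header
#'   or >= 15 columns; override with `format`.
#' @param format `"auto"`, `"gaf"` or `"tsv"`.
#' @param evidence evidence-code whitelist; `NULL` keeps everything.
#'   Defaults to the experimental codes
#'   EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC.
#' @return Named list: protein id -> character vector of annotated term ids
#'   (unpropagated). The evidence codes are retained in the
#'   `"evidence"` attribute as a data.frame (protein, term, evidence).
#' @export
read_annotations <- function(path, format = c("auto", "gaf", "tsv"),
                             evidence = EXPERIMENTAL_EVIDENCE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(body)) return(structure(list(), evidence = data.frame(
    protein = character(0), term = character(0), evidence = character(0))))
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (format == "auto")
    format <- if (any(startsWith(lines, "!gaf-version")) || ncol1 >= 15) "gaf" else "tsv"
  cols <- if (format == "gaf") c(2L, 5L, 7L) else c(1L, 2L, 3L)
  bad <- which(lengths(fields) < max(cols))
  if (length(bad)) stop("malformed annotation row at line ",
                        which(lines == body[bad[1]])[1])
  df <- data.frame(protein = vapply(fields, `[[`, "", cols[1]),
                   term = vapply(fields, `[[`, "", cols[2]),
                   evidence = vapply(fields, `[[`, "", cols[3]),
                   stringsAsFactors = FALSE)
  if (!is.null(evidence)) df <- df[df$evidence %in% evidence, , drop = FALSE]
  ann <- lapply(split(df$term, df$protein), function(x) sort(unique(x)))
  structure(ann[order(names(ann))], evidence = df)
}

#' Write annotations as a 3-column TSV
#'
#' @param ann named list protein -> term ids.
#' @param path output path.
#' @param evidence evidence code written for every row (fixtures are
#'   synthetic, so a single experimental code is used by default).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, evidence = "IDA") {
  rows <- unlist(lapply(names(ann), function(p) {
    if (!length(ann[[p]])) return(character(0))
    paste(p, ann[[p]], evidence, sep = "\t")
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}
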
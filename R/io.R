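## Readers/writers shared by all modules: XYZ/PDB conformations, TSV
## tables with JSON metadata sidecars, and flat key-value configuration.

.coordsOf <- function(x) {
  if (is(x, "LatticeChain")) return(coords(x))
  if (is(x, "FiberGeometry")) return(nucleosomeCenters(x))
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("expected a LatticeChain, FiberGeometry or n x 3 matrix",
       call. = FALSE)
}

#' Write a conformation to XYZ or PDB
#'
#' XYZ: bead count line, comment line, then one \code{C x y z} record per
#' bead, written at full double precision so that reading the file back
#' with \code{\link{readXYZ}} reproduces the coordinates bit-exactly.
#' PDB: minimal HETATM records, 1-based serial and residue numbering, a
#' single chain, coordinates converted from nm to Angstrom (10 A/nm) with
#' the fixed-width \%8.3f PDB coordinate format.
#'
#' @param x a \code{\linkS4class{LatticeChain}},
#'   \code{\linkS4class{FiberGeometry}} or numeric \code{n x 3} matrix
#'   (coordinates in nm for PDB output).
#' @param path output file path.
#' @param format \code{"xyz"} or \code{"pdb"}.
#' @param comment comment line for XYZ output.
#' @return the path, invisibly.
#' @export
writeConformation <- function(x, path, format = c("xyz", "pdb"),
                              comment = "chromfold conformation") {
  format <- match.arg(format)
  xyz <- .coordsOf(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    writeLines(as.character(nrow(xyz)), con)
    writeLines(comment, con)
    writeLines(sprintf("C %s %s %s",
                       formatC(xyz[, 1L], digits = 17, format = "g"),
                       formatC(xyz[, 2L], digits = 17, format = "g"),
                       formatC(xyz[, 3L], digits = 17, format = "g")), con)
  } else {
    a <- xyz * 10  # nm -> Angstrom
    writeLines(sprintf(
      "HETATM%5d  C   BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(a)), seq_len(nrow(a)), a[, 1L], a[, 2L], a[, 3L]), con)
    writeLines("END", con)
  }
  invisible(path)
}

#' Read an XYZ conformation
#'
#' @param path an XYZ file written by \code{\link{writeConformation}} (or
#'   any count/comment/records XYZ file).
#' @return numeric matrix with 3 columns.
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1L])
  if (is.na(n) || length(lines) < n + 2L)
    stop("malformed XYZ file: bad atom count", call. = FALSE)
  rec <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  out <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(out)))
    stop("malformed XYZ file: non-numeric coordinates", call. = FALSE)
  out
}

#' Write a TSV result table with a JSON metadata sidecar
#'
#' Tab-separated with a header row, '.' decimal separator and fixed column
#' order. If a schema (character vector of column names) is supplied the
#' table must match it exactly. A sidecar file \code{<path>.meta.json}
#' records the package version, the supplied metadata (configuration,
#' resolved seeds, ...) and the column schema, so any result file can be
#' regenerated from its own sidecar.
#'
#' @param rows a data.frame (zero rows allowed: header-only output).
#' @param path output TSV path.
#' @param schema optional character vector of required column names in
#'   order.
#' @param metadata named list stored in the sidecar (e.g.
#'   \code{list(seed = 42)}).
#' @return the path, invisibly.
#' @export
writeTable <- function(rows, path, schema = NULL, metadata = list()) {
  if (!is.data.frame(rows)) stop("rows must be a data.frame", call. = FALSE)
  if (!is.null(schema) && !identical(names(rows), as.character(schema)))
    stop(sprintf("table columns (%s) do not match the schema (%s)",
                 paste(names(rows), collapse = ", "),
                 paste(schema, collapse = ", ")), call. = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              dec = ".")
  sidecar <- list(package = "chromfold",
                  version = as.character(packageVersion("chromfold")),
                  columns = names(rows),
                  metadata = metadata)
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Resolve a run configuration from defaults, file and flag overrides
#'
#' Configuration is a flat key-value mapping. Values come from, in
#' increasing precedence: the supplied defaults, a YAML-compatible config
#' file, and command-line style overrides. Unknown keys are a hard error
#' listing the accepted keys; per-key validators produce errors naming the
#' violated constraint.
#'
#' @param defaults named list of all accepted keys and their defaults.
#' @param file optional path to a flat YAML config file.
#' @param overrides named list (or \code{c(key = value)}) of overrides,
#'   e.g. parsed from flags; character values are coerced to the type of
#'   the default.
#' @param validators optional named list of functions; each receives the
#'   resolved value and returns \code{TRUE} or a string describing the
#'   violated constraint.
#' @return named list of resolved values with attribute
#'   \code{"overridden"} listing keys changed from their defaults.
#' @examples
#' parseConfig(list(lp = 50, n = 100L), overrides = list(lp = "280"))
#' @export
parseConfig <- function(defaults, file = NULL, overrides = list(),
                        validators = list()) {
  if (is.null(names(defaults)) || any(names(defaults) == ""))
    stop("defaults must be a fully named list", call. = FALSE)
  cfg <- defaults
  apply_layer <- function(cfg, layer, what) {
    if (length(layer) == 0L) return(cfg)
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown) > 0L)
      stop(sprintf("unknown %s key(s): %s; accepted keys: %s", what,
                   paste(unknown, collapse = ", "),
                   paste(names(defaults), collapse = ", ")), call. = FALSE)
    for (k in names(layer)) {
      v <- layer[[k]]
      d <- defaults[[k]]
      if (is.character(v) && !is.character(d)) {
        v <- if (is.logical(d)) as.logical(v) else as.numeric(v)
        if (is.numeric(d) && is.integer(d)) v <- as.integer(v)
      }
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file),
                                 call. = FALSE)
    cfg <- apply_layer(cfg, .readFlatConfig(file), "config-file")
  }
  cfg <- apply_layer(cfg, as.list(overrides), "override")
  for (k in names(validators)) {
    res <- validators[[k]](cfg[[k]])
    if (!isTRUE(res))
      stop(sprintf("invalid value for '%s': %s", k, res), call. = FALSE)
  }
  changed <- names(defaults)[!vapply(names(defaults), function(k)
    identical(cfg[[k]], defaults[[k]]), logical(1))]
  structure(cfg, overridden = changed)
}

## flat "key: value" config reader. Keys are taken verbatim (so short
## keys like "n" or "y" are never reinterpreted as YAML booleans); scalar
## values are parsed with the YAML scalar rules.
.readFlatConfig <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0)
      stop(sprintf("malformed config line (expected 'key: value'): %s", ln),
           call. = FALSE)
    key <- trimws(substring(ln, 1L, m - 1L))
    val <- trimws(substring(ln, m + 1L))
    out[[key]] <- yaml::yaml.load(val)
  }
  out
}
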
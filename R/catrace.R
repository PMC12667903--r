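#' Calpha trace objects
#'
#' A `ca_trace` is the package's universal structural currency: the ordered
#' sequence of alpha-carbon coordinates of one protein chain, indexed N to C.
#' Optional SCOPe-style hierarchy labels (`"class.fold.superfamily.family"`)
#' attach classification information used for contrastive training and
#' retrieval evaluation.
#'
#' @param coords numeric n x 3 matrix of Calpha coordinates in Angstrom,
#'   rows ordered from the N- to the C-terminus.
#' @param id character identifier.
#' @param labels optional sccs-style hierarchy string
#'   (`"class.fold.superfamily.family"`).
#' @param source optional provenance string (e.g. a file path).
#' @return An object of class `ca_trace` with fields `id`, `coords`,
#'   `labels` and `source`.
#' @examples
#' tr <- ca_trace(cbind(3.8 * (0:9), 0, 0), id = "toy")
#' trace_length(tr)
#' @export
ca_trace <- function(coords, id = "trace", labels = NULL, source = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 5L)
    stop("a Calpha trace needs at least 5 residues, got ", n)
  if (!all(is.finite(coords)))
    stop("coords contain non-finite values")
  step <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                          coords[-n, , drop = FALSE])^2))
  if (any(step < 1e-6))
    stop("consecutive Calpha positions coincide")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = as.character(id), coords = coords,
         labels = if (is.null(labels)) NULL else as.character(labels),
         source = source),
    class = "ca_trace")
}

#' @rdname ca_trace
#' @param x,trace a `ca_trace`.
#' @export
trace_length <- function(trace) nrow(trace$coords)

#' @rdname ca_trace
#' @param ... ignored.
#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s: %d residues%s\n", x$id, trace_length(x),
              if (is.null(x$labels)) "" else paste0(" [", x$labels, "]")))
  invisible(x)
}

#' Read a Calpha trace from a PDB or mmCIF file
#'
#' Extracts the alpha-carbon coordinates of one chain, in file (residue)
#' order. Alternate locations are resolved to the highest-occupancy
#' conformer (first seen on ties); residues without a Calpha atom are
#' skipped without renumbering.
#'
#' @param path path to a structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param chain chain identifier; default is the first chain in the file.
#' @return A [ca_trace].
#' @export
read_ca_trace <- function(path, format = c("auto", "pdb", "mmcif"),
                          chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  obj <- tryCatch(
    suppressWarnings(
      if (format == "mmcif") bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("unparseable structure file ", path, ": ",
                             conditionMessage(e)))
  at <- obj$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no Calpha atoms in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no Calpha atoms in chain ", chain, " of ", path)
  # altloc resolution: per residue keep highest occupancy, first seen on ties
  ins <- if ("insert" %in% names(at)) at$insert else rep(NA, nrow(at))
  ins[is.na(ins)] <- ""
  reskey <- paste(at$resno, ins, sep = "_")
  occ <- if ("o" %in% names(at)) at$o else rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  keep <- logical(nrow(at))
  for (key in unique(reskey)) {
    idx <- which(reskey == key)
    keep[idx[which.max(occ[idx])]] <- TRUE
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) < 5L)
    stop("fewer than 5 Calpha residues in ", path, " (chain ", chain, ")")
  ca_trace(cbind(at$x, at$y, at$z),
           id = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE),
           source = path)
}

#' Write a Calpha trace as a Calpha-only PDB file
#'
#' Coordinates are written at PDB precision (3 decimals), one `ATOM` record
#' per residue. Coordinates with absolute value >= 10000 Angstrom overflow
#' the fixed-width PDB coordinate field and are rejected.
#'
#' @param trace a [ca_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  if (any(abs(trace$coords) >= 10000 - 1e-9) || any(trace$coords <= -1000))
    stop("coordinates overflow the PDB 8.3 field")
  n <- trace_length(trace)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(trace$coords)),
                   resno = seq_len(n), resid = rep("GLY", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
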
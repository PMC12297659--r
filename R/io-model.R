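# Atomic-model I/O. Parsing of PDB and mmCIF is delegated to bio3d; this
# layer normalizes both dialects into the flat `atomic_model` atom table
# and applies the altloc policy.

#' Read an atomic model from PDB or mmCIF
#'
#' All ATOM/HETATM coordinate records are parsed; chain ids and residue
#' indices are preserved. Alternate-location duplicates are reduced to a
#' single conformer per (chain, residue, atom name): the highest-occupancy
#' record is kept, with ties broken by first encounter.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return An [atomic_model].
#' @export
read_atomic_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- if (format == "cif")
    suppressWarnings(bio3d::read.cif(path))
  else
    suppressMessages(bio3d::read.pdb(path, rm.alt = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  occ <- at$o
  occ[is.na(occ)] <- 1
  df <- data.frame(
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    resname = at$resid,
    atom = at$elety,
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  # altloc policy: highest occupancy wins, first encountered wins ties
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) {
    ord <- order(factor(key, levels = unique(key)), -df$occupancy,
                 seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$chain, df$resno, df$atom)), , drop = FALSE]
    df <- df[order(match(paste(df$chain, df$resno, df$atom), unique(key))), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  atomic_model(df)
}

#' Write an atomic model as PDB
#'
#' @param model an [atomic_model].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_atomic_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords_of(model))),
                   resno = model$resno, chain = model$chain,
                   resid = model$resname, elety = model$atom,
                   o = model$occupancy, b = model$b,
                   elesy = model$element)
  invisible(path)
}
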
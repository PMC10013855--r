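#' Define a residue group
#'
#' Named residue selection used for geometric centers, contacts, fitting and
#' clustering. Selections address residues by PDB author numbering, optionally
#' restricted to a chain, with an atom-subset rule applied on resolution.
#' Heavy atoms are the default: the source figures omit hydrogens and
#' heavy-atom centers are robust to hydrogen placement.
#'
#' @param name Group name (e.g. "GsaAH", "alpha5", "ICL3", "ligand").
#' @param resno Integer vector of residue numbers.
#' @param chain Optional chain id; `NULL` matches any chain.
#' @param subset Atom-subset rule: "heavy" (non-hydrogen, default),
#'   "calpha" (CA atoms), or "all".
#' @return An object of class `residue_group`.
#' @export
residue_group <- function(name, resno, chain = NULL,
                          subset = c("heavy", "calpha", "all")) {
  subset <- match.arg(subset)
  resno <- unique(as.integer(resno))
  if (length(resno) == 0) stop("residue group '", name, "' is empty")
  structure(list(name = name, resno = resno, chain = chain, subset = subset),
            class = "residue_group")
}

#' @export
print.residue_group <- function(x, ...) {
  cat(sprintf("residue_group '%s': %d residues%s, subset = %s\n",
              x$name, length(x$resno),
              if (is.null(x$chain)) "" else paste0(" (chain ", x$chain, ")"),
              x$subset))
  invisible(x)
}

#' Resolve a residue group to atom indices
#'
#' @param top A [topology()].
#' @param group A [residue_group()].
#' @return Integer vector of row indices into the topology.
#' @export
resolve_group <- function(top, group) {
  stopifnot(inherits(top, "topology"), inherits(group, "residue_group"))
  sel <- top$resno %in% group$resno
  if (!is.null(group$chain)) sel <- sel & top$chain %in% group$chain
  found <- unique(top$resno[sel])
  missing <- setdiff(group$resno, found)
  if (length(missing) > 0) {
    stop("residue group '", group$name, "': residues not in topology: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  sel <- switch(group$subset,
    heavy  = sel & toupper(top$element) != "H",
    calpha = sel & top$atom_name == "CA",
    all    = sel
  )
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("residue group '", group$name,
         "': no atoms left after subset rule '", group$subset, "'")
  }
  idx
}

#' Read named residue groups from a YAML config
#'
#' The config maps group names to a chain, residue ranges and an optional
#' atom-subset rule, e.g.
#' ```yaml
#' GsaAH:    {chain: A, residues: "88-202", subset: heavy}
#' alpha5:   {chain: A, residues: "370-394"}
#' receptor: {chain: R, residues: "30-230, 263-340"}   # ICL3 excluded
#' ligand:   {chain: L, residues: "1"}
#' ```
#' Residue ranges are 1-based author numbering; exclusions (such as a receptor
#' without its intracellular loops) are expressed by listing the kept ranges.
#'
#' @param path Path to the YAML file.
#' @return Named list of [residue_group()] objects.
#' @export
read_groups_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("groups config must be a named mapping")
  }
  out <- lapply(names(cfg), function(nm) {
    g <- cfg[[nm]]
    if (is.null(g$residues)) stop("group '", nm, "' lacks a 'residues' field")
    residue_group(
      name = nm,
      resno = parse_residue_ranges(g$residues),
      chain = g$chain,
      subset = g$subset %||% "heavy"
    )
  })
  names(out) <- names(cfg)
  out
}

#' Parse a residue-range string
#'
#' Accepts forms like `"161"`, `"88-202"`, `"30-230, 263-340"` or a numeric
#' vector, returning the explicit residue numbers.
#'
#' @param x Range string or numeric vector.
#' @return Integer vector of residue numbers.
#' @export
parse_residue_ranges <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- trimws(strsplit(as.character(x), ",")[[1]])
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (length(ab) != 2 || anyNA(ab) || ab[1] > ab[2]) {
        stop("bad residue range: '", p, "'")
      }
      ab[1]:ab[2]
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop("bad residue number: '", p, "'")
      v
    }
  }))
  as.integer(out)
}
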
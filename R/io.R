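## Exporters: VTK XML unstructured grids (VTU) for meshes and field
## snapshots, VTP polylines for the t-tubule network, a truss/membrane
## sidecar in JSON, YAML run configuration, and CSV observable tables.
## The writers emit plain-ASCII VTK XML (no R package provides VTK output).

xml_darray <- function(name, x, ncomp = 1, type = "Float64") {
  paste0('<DataArray type="', type, '" Name="', name,
         '" NumberOfComponents="', ncomp, '" format="ascii">\n',
         paste(format(x, digits = 9, scientific = TRUE, trim = TRUE),
               collapse = " "),
         "\n</DataArray>")
}

#' Write a mesh or field snapshot as a VTU file
#'
#' Unstructured-grid XML VTK file with the hexahedral elements, integer
#' compartment labels as cell data, and optional nodal fields as point
#' data.  A sidecar JSON (same path with extension .json) stores the truss
#' network and the membrane node pairing, which have no VTU representation.
#'
#' @param mesh a \code{tricell_mesh}.
#' @param file output path (.vtu).
#' @param point_data named list of nodal vectors (length n nodes, or
#'   n x 3 matrices).
#' @param cell_data named list of per-element vectors.
#' @param sidecar write the truss/membrane JSON sidecar.
#' @return the file path, invisibly.
#' @export
write_mesh_vtu <- function(mesh, file, point_data = list(),
                           cell_data = list(), sidecar = TRUE) {
  n <- nrow(mesh$nodes); e <- nrow(mesh$hex)
  parts <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, e),
    "<Points>", xml_darray("Points", t(mesh$nodes), 3), "</Points>",
    "<Cells>",
    xml_darray("connectivity", t(mesh$hex) - 1L, 1, "Int64"),
    xml_darray("offsets", seq_len(e) * 8L, 1, "Int64"),
    xml_darray("types", rep(12L, e), 1, "UInt8"),
    "</Cells>")
  cd <- c(list(compartment = as.integer(mesh$label)), cell_data)
  parts <- c(parts, "<CellData>")
  for (nm in names(cd)) {
    ty <- if (is.integer(cd[[nm]])) "Int32" else "Float64"
    parts <- c(parts, xml_darray(nm, cd[[nm]], 1, ty))
  }
  parts <- c(parts, "</CellData>")
  if (length(point_data)) {
    parts <- c(parts, "<PointData>")
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) parts <- c(parts, xml_darray(nm, t(v), ncol(v)))
      else parts <- c(parts, xml_darray(nm, v, 1))
    }
    parts <- c(parts, "</PointData>")
  }
  parts <- c(parts, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(parts, file)
  if (sidecar) {
    side <- list(
      truss = list(nodes = mesh$truss$nodes, elems = mesh$truss$elems,
                   radius = mesh$truss$radius),
      membrane = mesh$membrane,
      boundary_tags = mesh$boundary_tags,
      fractions_requested = unclass(mesh$fractions_requested))
    jsonlite::write_json(side, sub("\\.vtu$", ".json", file),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(file)
}

#' Write the t-tubule network as a VTP polyline file
#'
#' @param mesh a \code{tricell_mesh} with a truss network.
#' @param file output path (.vtp).
#' @param point_data named list of per-truss-node vectors (pressures,
#'   lumen concentrations, potentials ...).
#' @return the file path, invisibly.
#' @export
write_truss_vtp <- function(mesh, file, point_data = list()) {
  tn <- mesh$truss$nodes; te <- mesh$truss$elems
  if (nrow(tn) == 0) stop("mesh has no truss network")
  parts <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    "<PolyData>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfLines="%d">',
            nrow(tn), nrow(te)),
    "<Points>", xml_darray("Points", t(as.matrix(tn[, c("x", "y", "z")])), 3),
    "</Points>",
    "<Lines>",
    xml_darray("connectivity", t(cbind(te$a, te$b)) - 1L, 1, "Int64"),
    xml_darray("offsets", seq_len(nrow(te)) * 2L, 1, "Int64"),
    "</Lines>")
  if (length(point_data)) {
    parts <- c(parts, "<PointData>")
    for (nm in names(point_data))
      parts <- c(parts, xml_darray(nm, point_data[[nm]], 1))
    parts <- c(parts, "</PointData>")
  }
  parts <- c(parts, "</Piece>", "</PolyData>", "</VTKFile>")
  writeLines(parts, file)
  invisible(file)
}

#' Write a field snapshot series entry
#'
#' Writes the nodal fields of a state (potentials, concentrations mapped
#' back to grid nodes, displacement) as a VTU time-series member.
#'
#' @param model a \code{tricell_model}.
#' @param state a model state.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_state_vtu <- function(model, state, file) {
  mesh <- model$mesh
  n <- nrow(mesh$nodes)
  grid_of <- function(dofmap, v) {
    out <- rep(NA_real_, n)
    out[which(!is.na(dofmap))] <- v[dofmap[!is.na(dofmap)]]
    out
  }
  pd <- list(Psi_i = grid_of(mesh$intra_dof, state$Psi_i),
             Psi_e = grid_of(mesh$extra_dof, state$Psi_e))
  for (s in colnames(state$Ci)) {
    pd[[paste0("C_", s, "_i")]] <- grid_of(mesh$intra_dof, state$Ci[, s])
    pd[[paste0("C_", s, "_e")]] <- grid_of(mesh$extra_dof, state$Ce[, s])
  }
  if (!is.null(state$U)) {
    U <- matrix(0, n, 3)
    ii <- which(!is.na(mesh$intra_dof))
    U[ii, ] <- matrix(state$U, ncol = 3, byrow = TRUE)[mesh$intra_dof[ii], ]
    pd$u <- U
  }
  cd <- list()
  if (!is.null(state$P)) {
    P_all <- numeric(nrow(mesh$hex)); P_all[which(mesh$is_intra)] <- state$P
    cd$P_w <- P_all
  }
  write_mesh_vtu(mesh, file, point_data = pd, cell_data = cd,
                 sidecar = FALSE)
}

#' Write an observable table as CSV with units in the header
#'
#' @param observables data.frame from a \code{tricell_result}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_observables_csv <- function(observables, file) {
  units <- vapply(names(observables), function(nm) {
    if (nm == "t") "ms"
    else if (startsWith(nm, "V_")) "mV"
    else if (startsWith(nm, "I_")) "A_per_F"
    else if (startsWith(nm, "Ca") || startsWith(nm, "Cmean")) "mM"
    else if (startsWith(nm, "w_truss")) "um_per_ms"
    else if (startsWith(nm, "tension")) "kPa"
    else ""
  }, "")
  hdr <- paste0(names(observables),
                ifelse(units == "", "", paste0("_", units)))
  utils::write.table(stats::setNames(observables, hdr), file, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a YAML run configuration
#'
#' Builds the geometry spec, compartment fractions, material parameters,
#' protocol and stepping configuration from a single YAML file with
#' top-level blocks \code{geometry}, \code{fractions}, \code{material},
#' \code{protocol}, \code{stepping} (all optional; defaults otherwise).
#'
#' @param file YAML path.
#' @return list with elements \code{spec}, \code{fractions}, \code{params},
#'   \code{protocol}, \code{stepping}.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  bad <- setdiff(names(y), c("geometry", "fractions", "material",
                             "protocol", "stepping"))
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))
  cl <- function(f, args) do.call(f, args %||% list())
  g <- y$geometry %||% list()
  if (!is.null(g$cross_section)) g$cross_section <- as.numeric(g$cross_section)
  list(spec = cl(cell_geometry_spec, g),
       fractions = cl(compartment_fractions, y$fractions),
       params = cl(material_params, y$material),
       protocol = cl(protocol_config, y$protocol),
       stepping = cl(stepping_config, y$stepping))
}

#' Provenance block describing surrogate components
#'
#' Emitted with every CLI run: lists the model components that are reduced
#' surrogates rather than fitted formulations, with their key defaults.
#'
#' @return character vector of lines.
#' @export
provenance_block <- function() {
  c("surrogate components:",
    "  ionic model: reduced 6-current HH-style surrogate (guinea-pig-like AP)",
    "  CICR/SERCA/mitochondria: reduced kinetics behind the f_subcell interface",
    "  crossbridge: first-order Hill activation, tension = T_max * activation",
    "  t-tubule radius 0.125 um, shear modulus 10 kPa, osmotic coeff 0.9,",
    "  C_m 1.0 uF/cm^2: implementation defaults (not stated at the source)")
}
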
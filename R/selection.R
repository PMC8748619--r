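# Bond and frame-group selection: resolves a selection config (shipped
# CHARMM36 POPC preset or user YAML/JSON) against a trajectory topology.

#' Read a selection config
#'
#' @param path YAML or JSON selection config (see the shipped
#'   \code{popc_charmm36.yaml} preset for the schema: a \code{bonds} list
#'   with \code{site}, \code{resonance}, \code{C}, \code{H},
#'   \code{neighbors} entries and a named \code{groups} list with
#'   \code{atoms} and \code{kind}).
#' @return The config as a list.
#' @export
read_selection_config <- function(path) {
  if (!file.exists(path)) stop("selection config not found: ", path)
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}

#' The shipped CHARMM36 POPC selection preset
#'
#' H-C bonds of the choline head group (alpha, beta, gamma), glycerol
#' (g1, g2, g3), both acyl chains and the two C=O bonds, with libration
#' neighbor sets, plus the glycerol frame group (glycerol carbons and
#' oxygens) and per-chain groups excluding the carbonyl.
#'
#' @return Config list (same schema as [read_selection_config()]).
#' @export
popc_preset <- function() {
  read_selection_config(system.file("extdata", "popc_charmm36.yaml",
                                    package = "dynland", mustWork = TRUE))
}

#' Resolve bonds and frame atom groups against a topology
#'
#' Matches the config's atom names per residue instance, producing the
#' bond table (one row per H-C or C=O bond per molecule copy), per-bond
#' libration atom sets (the carbon and its directly bonded atoms), and the
#' named frame groups. Selection is by atom/residue name only, so it is
#' independent of atom ordering.
#'
#' @param traj A \code{trajectory_handle}.
#' @param config Config list (e.g. [popc_preset()]) or a path to one.
#' @return List with \code{bonds} (data frame: \code{C}, \code{H} atom
#'   indices, \code{site}, \code{resonance}, \code{resno}, \code{kind}),
#'   \code{libration} (list of atom index vectors, one per bond row) and
#'   \code{groups} (list of \code{name}, \code{resno}, \code{kind},
#'   \code{atoms}).
#' @export
resolve_selection <- function(traj, config) {
  if (is.character(config)) config <- read_selection_config(config)
  at <- traj$atoms
  sites <- vapply(config$bonds, function(b) b$site, character(1))
  if (anyDuplicated(sites)) {
    stop("duplicate site labels in selection config: ",
         paste(unique(sites[duplicated(sites)]), collapse = ", "))
  }
  resname <- config$resname %||% unique(at$resid)[1]
  resnos <- sort(unique(at$resno[at$resid == resname]))
  if (!length(resnos)) stop("no residue named ", resname, " in topology")
  bonds <- list(); libr <- list()
  for (b in config$bonds) {
    cnames <- unlist(b$C)
    # H may be one set shared by all carbons, or a nested list pairing each
    # carbon with its own hydrogens
    paired <- is.list(b$H) && length(cnames) > 1 &&
      length(b$H) == length(cnames)
    found_any_c <- FALSE
    for (rn in resnos) {
      ridx <- which(at$resno == rn & at$resid == resname)
      for (ic in seq_along(cnames)) {
        cn <- cnames[ic]
        hnames <- if (paired) unlist(b$H[[ic]]) else unlist(b$H)
        ci <- ridx[at$name[ridx] == cn]
        if (!length(ci)) next
        found_any_c <- TRUE
        hi <- ridx[at$name[ridx] %in% hnames]
        if (!length(hi)) {
          message("site ", b$site, " (residue ", rn, "): carbon ", cn,
                  " has no partner atom; bond skipped")
          next
        }
        nb <- ridx[at$name[ridx] %in% unlist(b$neighbors)]
        for (h in hi) {
          bonds[[length(bonds) + 1L]] <- data.frame(
            C = ci[1], H = h, site = b$site,
            resonance = b$resonance %||% b$site, resno = rn,
            kind = b$kind %||% "HC", stringsAsFactors = FALSE)
          libr[[length(libr) + 1L]] <- unique(c(ci[1], hi, nb))
        }
      }
    }
    if (!found_any_c) {
      stop("selection pattern matched zero atoms: site ", b$site,
           " (C atom ", paste(cnames, collapse = "/"), ")")
    }
  }
  groups <- list()
  for (gn in names(config$groups %||% list())) {
    g <- config$groups[[gn]]
    for (rn in resnos) {
      ridx <- which(at$resno == rn & at$resid == resname)
      gi <- ridx[at$name[ridx] %in% unlist(g$atoms)]
      if (length(gi) < 3) {
        stop("frame group ", gn, " matched fewer than 3 atoms in residue ",
             rn)
      }
      groups[[length(groups) + 1L]] <- list(name = gn, resno = rn,
                                            kind = g$kind %||% "rigid_align",
                                            atoms = gi)
    }
  }
  list(bonds = do.call(rbind, bonds), libration = libr, groups = groups)
}
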
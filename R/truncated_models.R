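# Construction of the three truncated QM models of a [2Fe-2S] site:
#   level 1 — cluster + ligand side chains from C-beta, methyl-capped;
#   level 2 — level 1 residues in full + backbone of the residues spanning
#             between consecutive ligands (side chains replaced by H),
#             ACE/NME-capped;
#   level 3 — cluster + every residue with any atom within 4 A of a
#             cluster-core atom, ACE/NME-capped.

.MODEL3_RADIUS <- 4.0    # Angstrom, atom-to-atom, whole residue included
.BACKBONE_ELETY <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")
.CAP_H_LENGTH <- 1.09    # Angstrom, standard C-H

#' Build a truncated QM model of a cluster site
#'
#' Implements the three truncation levels used for quantum-chemistry
#' calculations on a [2Fe-2S] centre. Level 1 keeps the inorganic cluster
#' and the ligand side chains from C-beta, saturating each C-beta with an
#' added hydrogen (methyl cap). Level 2 keeps the full ligating residues
#' plus the main-chain atoms of residues spanning between consecutive
#' ligands in sequence, replacing spanning side chains by a hydrogen on
#' C-alpha, with acetyl (ACE) and N-methyl (NME) terminal caps. Level 3
#' keeps the cluster and every residue having any atom within `radius` of
#' any cluster-core atom (2 Fe + 2 bridging S), ACE/NME-capped. Added
#' hydrogens use standard bond lengths along the bond being cut.
#'
#' @param site A `cluster_site` from [detect_cluster_sites()].
#' @param structure The bio3d `pdb` object (or path) the site came from.
#' @param level Truncation level, 1, 2 or 3.
#' @param state `"oxidized"` or `"reduced"`; sets the stored formal charge
#'   (-2 / -3 for a 3Cys:1His centre with thiolate ligands).
#' @param radius Inclusion radius for level 3 (Angstrom, default 4.0).
#' @return A `truncated_model`: atoms (with a `source` column marking
#'   cluster/side-chain/backbone/cap origin), cap list, net formal charge
#'   and spin-state label.
#' @export
build_model <- function(site, structure, level = c(1L, 2L, 3L),
                        state = c("oxidized", "reduced"),
                        radius = .MODEL3_RADIUS) {
  level <- as.integer(level[1])
  stopifnot(level %in% 1:3)
  state <- match.arg(state)
  pdb <- as_pdb(structure)
  at <- pdb$atom
  at$elem <- pdb_elements(pdb)
  at$elety <- trimws(at$elety)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  core_idx <- c(site$fe$idx, site$bridge$idx)
  lig_res <- unique(site$ligands[, c("chain", "resno", "resid")])

  take <- function(idx, source) {
    data.frame(elety = at$elety[idx], elem = at$elem[idx],
               resid = at$resid[idx], resno = at$resno[idx],
               chain = at$chain[idx],
               x = xyz[idx, 1], y = xyz[idx, 2], z = xyz[idx, 3],
               source = source, stringsAsFactors = FALSE)
  }
  res_atoms <- function(chain, resno) {
    which(at$chain == chain & at$resno == resno & at$type == "ATOM")
  }
  cap_h <- function(anchor, toward, resno, chain) {
    # H placed along anchor -> toward at standard C-H length
    u <- toward - anchor
    u <- u / sqrt(sum(u^2))
    p <- anchor + .CAP_H_LENGTH * u
    data.frame(elety = "H", elem = "H", resid = "CAP", resno = resno,
               chain = chain, x = p[1], y = p[2], z = p[3],
               source = "cap", stringsAsFactors = FALSE)
  }

  atoms <- take(core_idx, "cluster")
  caps <- data.frame()

  if (level == 1L) {
    for (r in seq_len(nrow(lig_res))) {
      idx <- res_atoms(lig_res$chain[r], lig_res$resno[r])
      side <- idx[!(at$elety[idx] %in% .BACKBONE_ELETY) &
                    at$elety[idx] != "CB"]
      cb <- idx[at$elety[idx] == "CB"]
      ca <- idx[at$elety[idx] == "CA"]
      atoms <- rbind(atoms, take(c(cb, side), "sidechain"))
      if (length(cb) == 1 && length(ca) == 1) {
        h <- cap_h(xyz[cb, ], xyz[ca, ], lig_res$resno[r], lig_res$chain[r])
        atoms <- rbind(atoms, h)
        caps <- rbind(caps, data.frame(type = "methyl-H",
                                       chain = lig_res$chain[r],
                                       anchor_resno = lig_res$resno[r]))
      }
    }
  } else if (level == 2L) {
    for (r in seq_len(nrow(lig_res))) {
      atoms <- rbind(atoms,
                     take(res_atoms(lig_res$chain[r], lig_res$resno[r]),
                          "ligand"))
    }
    for (ch in unique(lig_res$chain)) {
      resnos <- sort(lig_res$resno[lig_res$chain == ch])
      if (length(resnos) < 2) next
      for (k in seq_len(length(resnos) - 1)) {
        span <- setdiff(seq(resnos[k], resnos[k + 1]), resnos)
        for (rn in span) {
          idx <- res_atoms(ch, rn)
          if (length(idx) == 0) {
            stop(sprintf(
              "chain break inside level-2 span: chain %s residue %d missing",
              ch, rn))
          }
          bb <- idx[at$elety[idx] %in% c("N", "CA", "C", "O")]
          atoms <- rbind(atoms, take(bb, "backbone"))
          ca <- idx[at$elety[idx] == "CA"]
          cb <- idx[at$elety[idx] == "CB"]
          if (length(ca) == 1 && length(cb) == 1) {
            atoms <- rbind(atoms, cap_h(xyz[ca, ], xyz[cb, ], rn, ch))
          }
        }
      }
      caps <- rbind(caps,
                    data.frame(type = c("ACE", "NME"), chain = ch,
                               anchor_resno = range(resnos)))
    }
  } else {
    core_xyz <- xyz[core_idx, , drop = FALSE]
    prot <- which(at$type == "ATOM" & at$resid != "HOH")
    if (length(prot) > 0) {
      mind <- vapply(prot, function(i) {
        min(colSums((t(core_xyz) - xyz[i, ])^2))
      }, numeric(1))
      near <- prot[mind <= radius^2]
      inc_res <- unique(at[near, c("chain", "resno")])
      for (r in seq_len(nrow(inc_res))) {
        atoms <- rbind(atoms,
                       take(res_atoms(inc_res$chain[r], inc_res$resno[r]),
                            "residue"))
      }
      for (ch in unique(inc_res$chain)) {
        caps <- rbind(caps,
                      data.frame(type = c("ACE", "NME"), chain = ch,
                                 anchor_resno =
                                   range(inc_res$resno[inc_res$chain == ch])))
      }
    }
  }

  charge <- if (site$class == "3Cys:1His") {
    if (state == "oxidized") -2L else -3L
  } else NA_integer_
  structure(list(level = level, atoms = atoms, caps = caps,
                 net_charge = charge, state = state,
                 spin = "antiferromagnetic (broken-symmetry)"),
            class = "truncated_model")
}

#' @export
print.truncated_model <- function(x, ...) {
  cat(sprintf("truncated_model level %d (%s): %d atoms, charge %s\n",
              x$level, x$state, nrow(x$atoms),
              ifelse(is.na(x$net_charge), "NA", x$net_charge)))
  invisible(x)
}

#' Write a truncated model as PDB plus a text manifest
#'
#' @param model A `truncated_model`.
#' @param path Output PDB path; the manifest is written next to it with a
#'   `.manifest.txt` suffix.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  a <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$resid %in% c("FES", "CAP"), "HETATM", "ATOM"),
    seq_len(nrow(a)), substr(a$elety, 1, 4), substr(a$resid, 1, 3),
    ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    a$resno, a$x, a$y, a$z, 1.0, 0.0, toupper(a$elem))
  writeLines(c(lines, "END"), path)
  man <- c(sprintf("level: %d", model$level),
           sprintf("state: %s", model$state),
           sprintf("net_charge: %s", model$net_charge),
           sprintf("spin: %s", model$spin),
           "caps:",
           if (nrow(model$caps)) {
             sprintf("  %s chain %s anchor %d", model$caps$type,
                     model$caps$chain, model$caps$anchor_resno)
           } else "  none")
  writeLines(man, paste0(path, ".manifest.txt"))
  invisible(path)
}
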
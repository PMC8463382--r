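# [2Fe-2S] site detection in PDB structures, truncated QM-model
# construction (levels 1/2/3), redox geometry tables and superposition.
#
# Structure I/O goes through bio3d; coordinates are Angstrom in PDB frames
# and nm in every reported table.

.FE_DONOR_CUTOFF <- 2.6   # Angstrom; covers the longest reported bond
                          # (0.246 nm) with margin

as_pdb <- function(structure) {
  if (inherits(structure, "pdb")) return(structure)
  if (is.character(structure) && length(structure) == 1) {
    return(bio3d::read.pdb(structure, verbose = FALSE))
  }
  stop("structure must be a bio3d 'pdb' object or a PDB file path")
}

pdb_elements <- function(pdb) {
  ele <- pdb$atom$elesy
  if (is.null(ele) || all(is.na(ele)) || all(trimws(ele) == "")) {
    ele <- bio3d::atom2ele(pdb)
  }
  ele <- trimws(ele)
  paste0(toupper(substr(ele, 1, 1)), tolower(substring(ele, 2)))
}

#' Detect [2Fe-2S] cluster sites in a structure
#'
#' A site is a pair of Fe atoms sharing two bridging sulfides (each S within
#' the Fe-donor cutoff of both irons). Protein S/N/O atoms within the cutoff
#' of either iron become ligand donors. The His-bound iron is labelled
#' `Fe_Y`, the 2-Cys iron `Fe_X`; a site with 3 Cys thiolates and 1 His
#' imidazole nitrogen gets coordination class `"3Cys:1His"`. Fe atoms that
#' do not share two bridging sulfides with a partner are skipped with a
#' message.
#'
#' @param structure A bio3d `pdb` object or a PDB file path.
#' @param cutoff Fe-donor distance cutoff in Angstrom (default 2.6).
#' @return A list of `cluster_site` objects (possibly empty).
#' @export
detect_cluster_sites <- function(structure, cutoff = .FE_DONOR_CUTOFF) {
  pdb <- as_pdb(structure)
  at <- pdb$atom
  at$elem <- pdb_elements(pdb)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  fe_idx <- which(at$elem == "Fe")
  if (length(fe_idx) == 0) return(list())

  s_idx <- which(at$elem == "S")
  dist2 <- function(i, j) sum((xyz[i, ] - xyz[j, ])^2)
  cut2 <- cutoff^2

  sites <- list()
  used <- integer(0)
  if (length(fe_idx) >= 2) {
    pairs <- utils::combn(fe_idx, 2)
    for (p in seq_len(ncol(pairs))) {
      fe1 <- pairs[1, p]; fe2 <- pairs[2, p]
      if (fe1 %in% used || fe2 %in% used) next
      bridging <- s_idx[vapply(s_idx, function(s) {
        dist2(s, fe1) <= cut2 && dist2(s, fe2) <= cut2
      }, logical(1))]
      if (length(bridging) != 2) next
      site <- build_site(at, xyz, c(fe1, fe2), bridging, cutoff)
      if (!is.null(site)) {
        sites <- c(sites, list(site))
        used <- c(used, fe1, fe2)
      }
    }
  }
  orphans <- setdiff(fe_idx, used)
  if (length(orphans) > 0) {
    message(length(orphans),
            " Fe atom(s) without two shared bridging sulfides; skipped")
  }
  sites
}

# assemble one cluster_site from detected core atoms
build_site <- function(at, xyz, fe, bridging, cutoff) {
  protein <- at$type == "ATOM"
  donor_elem <- at$elem %in% c("S", "N", "O")
  cand <- which(protein & donor_elem)
  cand <- setdiff(cand, c(fe, bridging))
  cut2 <- cutoff^2

  d_fe <- vapply(cand, function(i) {
    d1 <- sum((xyz[i, ] - xyz[fe[1], ])^2)
    d2 <- sum((xyz[i, ] - xyz[fe[2], ])^2)
    c(d1, d2)
  }, numeric(2))
  keep <- which(apply(d_fe, 2, min) <= cut2)
  if (length(keep) == 0) return(NULL)
  cand <- cand[keep]
  which_fe <- apply(d_fe[, keep, drop = FALSE], 2, which.min)

  lig <- data.frame(
    donor_idx = cand,
    resid = at$resid[cand], resno = at$resno[cand], chain = at$chain[cand],
    donor_elety = trimws(at$elety[cand]), donor_elem = at$elem[cand],
    fe_local = which_fe,
    x = xyz[cand, 1], y = xyz[cand, 2], z = xyz[cand, 3],
    stringsAsFactors = FALSE
  )
  # one donor per residue: keep the closest donor atom of each residue
  dmin <- apply(d_fe[, keep, drop = FALSE], 2, min)
  ord <- order(dmin)
  lig <- lig[ord[!duplicated(paste(lig$resno, lig$chain)[ord])], , drop = FALSE]

  his_n <- lig$resid == "HIS" & lig$donor_elem == "N"
  fe_y_local <- if (any(his_n)) lig$fe_local[which(his_n)[1]] else NA_integer_
  n_cys <- sum(lig$resid == "CYS" & lig$donor_elem == "S")
  n_his <- sum(his_n)
  class <- if (n_cys == 3 && n_his == 1) "3Cys:1His" else {
    parts <- c(if (n_cys > 0) paste0(n_cys, "Cys"),
               if (n_his > 0) paste0(n_his, "His"))
    if (length(parts)) paste(parts, collapse = ":") else "unclassified"
  }

  # Fe_Y = His-bound iron when present, else second iron by index
  loc <- if (!is.na(fe_y_local)) c(setdiff(1:2, fe_y_local), fe_y_local) else 1:2
  fe_df <- data.frame(label = c("Fe_X", "Fe_Y"), idx = fe[loc],
                      x = xyz[fe[loc], 1], y = xyz[fe[loc], 2],
                      z = xyz[fe[loc], 3])
  br_df <- data.frame(label = c("S_1", "S_2"), idx = bridging,
                      x = xyz[bridging, 1], y = xyz[bridging, 2],
                      z = xyz[bridging, 3])
  lig$fe_label <- c("Fe_X", "Fe_Y")[match(lig$fe_local, loc)]

  # canonical ligand labels: Cys on Fe_X by resno, then Cys on Fe_Y, then His
  lig$label <- NA_character_
  cx <- which(lig$resid == "CYS" & lig$fe_label == "Fe_X")
  cx <- cx[order(lig$resno[cx])]
  if (length(cx)) lig$label[cx] <- paste0("S_Cys", seq_along(cx))
  cy <- which(lig$resid == "CYS" & lig$fe_label == "Fe_Y")
  cy <- cy[order(lig$resno[cy])]
  if (length(cy)) lig$label[cy] <- paste0("S_Cys", length(cx) + seq_along(cy))
  hy <- which(his_n)[1]
  if (!is.na(hy) && length(hy)) lig$label[hy] <- "N_His"
  other <- which(is.na(lig$label))
  if (length(other)) lig$label[other] <- paste0("X_", seq_along(other))

  structure(list(fe = fe_df, bridge = br_df, ligands = lig,
                 class = class, his_protonation = "unknown"),
            class = "cluster_site")
}

#' @export
print.cluster_site <- function(x, ...) {
  cat(sprintf("cluster_site: [2Fe-2S], class %s, %d ligand donor(s)\n",
              x$class, nrow(x$ligands)))
  cat("  ligands:", paste(sprintf("%s%d(%s)", x$ligands$resid,
                                  x$ligands$resno, x$ligands$label),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Canonical bond-length table of a cluster site
#'
#' Reports the eight canonical distances of the 3Cys:1His centre
#' (Fe_X/Fe_Y to each bridging sulfide and to their ligand donors), in nm.
#' Rows whose donor is missing are omitted with a warning.
#'
#' @param site A `cluster_site`.
#' @param state State label stored on the table (`"oxidized"`/`"reduced"`).
#' @return A `geometry_table` data frame with columns `bond` and `R_nm`.
#' @export
bond_geometry <- function(site, state = "unspecified") {
  fe <- site$fe
  pos <- function(df, lab) {
    r <- df[df$label == lab, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    as.numeric(r[1, c("x", "y", "z")])
  }
  want <- list(
    c("Fe_X", "S_1"), c("Fe_X", "S_2"),
    c("Fe_Y", "S_1"), c("Fe_Y", "S_2"),
    c("Fe_X", "S_Cys1"), c("Fe_X", "S_Cys2"),
    c("Fe_Y", "S_Cys3"), c("Fe_Y", "N_His")
  )
  rows <- lapply(want, function(w) {
    a <- pos(fe, w[1])
    b <- pos(site$bridge, w[2])
    if (is.null(b)) b <- pos(site$ligands, w[2])
    if (is.null(a) || is.null(b)) {
      warning("missing donor for bond ", w[1], "-", w[2], "; row omitted")
      return(NULL)
    }
    data.frame(bond = paste0(w[1], "-", w[2]),
               R_nm = sqrt(sum((a - b)^2)) / 10)
  })
  out <- do.call(rbind, rows)
  geometry_table(out$bond, out$R_nm, state = state)
}

#' Construct a geometry table
#'
#' @param bond Character bond labels (unique).
#' @param R_nm Bond lengths in nm (> 0).
#' @param Kr Optional bond force constants in kJ/mol nm^2.
#' @param state State label (e.g. `"oxidized"`, `"reduced"`).
#' @param source Free-text provenance label.
#' @return A `geometry_table` data frame.
#' @export
geometry_table <- function(bond, R_nm, Kr = NULL, state = "unspecified",
                           source = "neetkit") {
  stopifnot(!anyDuplicated(bond), all(R_nm > 0))
  out <- data.frame(bond = as.character(bond), R_nm = as.numeric(R_nm))
  if (!is.null(Kr)) out$Kr <- as.numeric(Kr)
  structure(out, state = state, source = source,
            class = c("geometry_table", "data.frame"))
}

#' Read a geometry table from CSV
#'
#' Expects columns `bond`, `R_nm` and optionally `Kr`.
#'
#' @param path CSV file path.
#' @param state State label to attach.
#' @return A [geometry_table()].
#' @export
read_geometry_table <- function(path, state = "unspecified") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  geometry_table(df$bond, df$R_nm, Kr = df$Kr, state = state, source = path)
}

#' Per-bond redox differences between two geometry tables
#'
#' Matches bonds by label and reports reduced-minus-oxidized length changes
#' and, when force constants are present, reduced/oxidized K_r ratios. A
#' bond is flagged `weakened` when it lengthens (dR > 0) and its force
#' constant drops (ratio < 1) on reduction.
#'
#' @param ox,red `geometry_table`s with matching bond labels.
#' @return A data frame with columns `bond`, `R_ox_nm`, `R_red_nm`, `dR_nm`
#'   and, if available, `Kr_ox`, `Kr_red`, `Kr_ratio`, `weakened`.
#' @export
redox_delta_report <- function(ox, red) {
  if (!setequal(ox$bond, red$bond)) {
    miss <- c(setdiff(ox$bond, red$bond), setdiff(red$bond, ox$bond))
    stop("bond labels do not match: ", paste(miss, collapse = ", "))
  }
  m <- match(ox$bond, red$bond)
  out <- data.frame(bond = ox$bond,
                    R_ox_nm = ox$R_nm, R_red_nm = red$R_nm[m],
                    dR_nm = red$R_nm[m] - ox$R_nm)
  if (!is.null(ox$Kr) && !is.null(red$Kr)) {
    out$Kr_ox <- ox$Kr
    out$Kr_red <- red$Kr[m]
    out$Kr_ratio <- red$Kr[m] / ox$Kr
    out$weakened <- out$dR_nm > 0 & out$Kr_ratio < 1
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of matched
#' point sets, and reports the RMSD after the fit. Units follow the input
#' coordinates.
#'
#' @param A,B n x 3 coordinate matrices (B is fitted onto A).
#' @param selection Optional integer row selection applied to both sets.
#' @return List with `rmsd`, `rotation` (3x3, applied on the right),
#'   `translation`, and `B_fit` (all B rows transformed).
#' @export
superpose_rmsd <- function(A, B, selection = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.null(selection)) {
    As <- A[selection, , drop = FALSE]; Bs <- B[selection, , drop = FALSE]
  } else {
    As <- A; Bs <- B
  }
  if (nrow(As) != nrow(Bs)) stop("selections differ in length")
  if (nrow(As) < 3) stop("need at least 3 points to superpose")
  ca <- colMeans(As); cb <- colMeans(Bs)
  Ac <- sweep(As, 2, ca); Bc <- sweep(Bs, 2, cb)
  sv <- svd(crossprod(Bc, Ac))   # 3x3
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2) {
    stop("points are collinear or degenerate; superposition undefined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Bfit_sel <- Bc %*% R
  rmsd <- sqrt(mean(rowSums((Bfit_sel - Ac)^2)))
  B_fit <- sweep(sweep(B, 2, cb) %*% R, 2, ca, "+")
  list(rmsd = rmsd, rotation = R, translation = ca - cb %*% R, B_fit = B_fit)
}
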
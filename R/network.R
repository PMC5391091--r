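#' Build the stochastic reaction network of the BL model
#'
#' Constructs the full discrete reaction network for a receptor with
#' \code{M} methylation sites.  Level 0 is always inactive and unligated,
#' level \code{M} always active and unligated; each intermediate level
#' \code{m = 1..M-1} has four conformations: active/unligated,
#' inactive/ligated, CheR-bound (to the inactive, i.e. ligated form) and
#' CheB-bound (to the active form).  The reactions are, per level:
#' reversible ligand binding on intermediates (active unligated <->
#' inactive ligated), reversible CheR binding to inactive forms, reversible
#' CheB binding to active forms, and the irreversible catalytic steps
#' (CheR-bound at level m -> level m+1 releasing CheR; CheB-bound at level
#' m -> level m-1 releasing CheB).  Catalytic products enter the unligated
#' conformation of the destination level; ligand occupancy then
#' re-equilibrates on the fast binding time scale.
#'
#' For \code{M} sites this gives \code{4M} receptor conformations and
#' \code{5M - 1} reactions counting each reversible pair once
#' (\code{3M - 1} reversible pairs plus \code{2M} irreversible steps):
#' (8, 9) for M = 2, (12, 14) for M = 3, (16, 19) for M = 4.
#'
#' @param params a \code{\link{bl_params}} object.
#' @param rates a \code{\link{kinetic_rates}} object (defaults from
#'   \code{params}).
#' @return An object of class \code{bl_network} with elements
#'   \describe{
#'     \item{species}{data frame of receptor conformations (level, active
#'       flag, ligated flag, bound enzyme).}
#'     \item{enzymes}{names of the two free-enzyme species appended to the
#'       state vector ("Rf", "Bf").}
#'     \item{reactions}{data frame of elementary (irreversible) reactions
#'       with reactant/product indices into the full state vector, rate
#'       constants already expressed in propensity units, and a kind label.}
#'     \item{counts}{list with \code{n_species}, \code{n_reversible},
#'       \code{n_irreversible}, \code{n_reactions} (reversible pair counted
#'       once).}
#'     \item{init}{default initial state: all receptors unmethylated,
#'       unbound, inactive; free enzymes at \code{round(R0*conversion)} and
#'       \code{round(B0*conversion)} (at least 1 molecule each, with a
#'       warning if rounding from below).}
#'   }
#' @examples
#' net <- build_network(bl_params(M = 2))
#' net$counts
#' @export
build_network <- function(params, rates = kinetic_rates(params)) {
  M <- params$M
  if (M < 2 && params$L > 0)
    warning("for M = 1 the ligand concentration plays no role in the dynamics")

  sp <- list()
  add_sp <- function(name, level, active, ligated, bound) {
    sp[[length(sp) + 1L]] <<- data.frame(
      name = name, level = level, active = active,
      ligated = ligated, bound = bound, stringsAsFactors = FALSE)
  }
  # level 0: inactive, unligated; free or CheR-bound
  add_sp("m0",   0L, FALSE, FALSE, "none")
  add_sp("m0.R", 0L, FALSE, FALSE, "R")
  for (m in seq_len(M - 1L)) {
    add_sp(sprintf("m%da",   m), m, TRUE,  FALSE, "none")
    add_sp(sprintf("m%diL",  m), m, FALSE, TRUE,  "none")
    add_sp(sprintf("m%diL.R", m), m, FALSE, TRUE, "R")
    add_sp(sprintf("m%da.B",  m), m, TRUE,  FALSE, "B")
  }
  add_sp(sprintf("m%da",   M), M, TRUE, FALSE, "none")
  add_sp(sprintf("m%da.B", M), M, TRUE, FALSE, "B")
  species <- do.call(rbind, sp)
  ns <- nrow(species)
  idx <- function(name) match(name, species$name)
  iR <- ns + 1L   # free CheR
  iB <- ns + 2L   # free CheB

  omega <- params$conversion   # molecules per uM: scales bimolecular rates
  rx <- list()
  add_rx <- function(kind, reversible_id, r1, r2, p1, p2, c) {
    rx[[length(rx) + 1L]] <<- data.frame(
      kind = kind, pair = reversible_id,
      r1 = r1, r2 = ifelse(is.na(r2), NA_integer_, r2),
      p1 = p1, p2 = ifelse(is.na(p2), NA_integer_, p2),
      c = c, stringsAsFactors = FALSE)
  }
  pair <- 0L
  # CheR binding/unbinding: inactive forms (level 0 free; intermediate ligated)
  bindR <- function(free_name, bound_name) {
    pair <<- pair + 1L
    add_rx("R_bind",   pair, idx(free_name), iR, idx(bound_name), NA, rates$k_plus / omega)
    add_rx("R_unbind", pair, idx(bound_name), NA, idx(free_name), iR, rates$k_minus)
  }
  bindB <- function(free_name, bound_name) {
    pair <<- pair + 1L
    add_rx("B_bind",   pair, idx(free_name), iB, idx(bound_name), NA, rates$k_plus_p / omega)
    add_rx("B_unbind", pair, idx(bound_name), NA, idx(free_name), iB, rates$k_minus_p)
  }
  bindR("m0", "m0.R")
  for (m in seq_len(M - 1L)) {
    nm <- function(s) sprintf(s, m)
    # ligand binding: active unligated <-> inactive ligated (external L)
    pair <- pair + 1L
    add_rx("L_bind",   pair, idx(nm("m%da")), NA, idx(nm("m%diL")), NA,
           rates$k_a * params$L)
    add_rx("L_unbind", pair, idx(nm("m%diL")), NA, idx(nm("m%da")), NA, rates$k_d)
    bindR(nm("m%diL"), nm("m%diL.R"))
    bindB(nm("m%da"),  nm("m%da.B"))
  }
  bindB(sprintf("m%da", M), sprintf("m%da.B", M))
  # catalysis: CheR-bound level m -> unligated form of level m+1, CheR freed
  dest_up <- function(m) if (m + 1L == M) sprintf("m%da", M) else sprintf("m%da", m + 1L)
  add_rx("methylation", NA, idx("m0.R"), NA, idx(dest_up(0L)), iR, params$nu_r)
  for (m in seq_len(M - 1L)) {
    add_rx("methylation", NA, idx(sprintf("m%diL.R", m)), NA,
           idx(dest_up(m)), iR, params$nu_r)
    dest <- if (m - 1L == 0L) "m0" else sprintf("m%da", m - 1L)
    add_rx("demethylation", NA, idx(sprintf("m%da.B", m)), NA,
           idx(dest), iB, params$nu_b)
  }
  add_rx("demethylation", NA, idx(sprintf("m%da.B", M)), NA,
         idx(sprintf("m%da", M - 1L)), iB, params$nu_b)
  reactions <- do.call(rbind, rx)

  n_rev <- max(reactions$pair, na.rm = TRUE)
  n_irr <- sum(is.na(reactions$pair))
  nR <- max(1L, as.integer(round(params$R0 * params$conversion)))
  nB <- max(1L, as.integer(round(params$B0 * params$conversion)))
  if (params$R0 > 0 && params$R0 * params$conversion < 0.5)
    warning("R0*conversion < 0.5 molecule; using 1 CheR molecule")
  if (params$R0 == 0) nR <- 0L
  init <- c(stats::setNames(integer(ns), species$name), Rf = nR, Bf = nB)
  init["m0"] <- receptor_count(params)

  structure(list(species = species, enzymes = c("Rf", "Bf"),
                 reactions = reactions,
                 counts = list(n_species = ns, n_reversible = n_rev,
                               n_irreversible = n_irr,
                               n_reactions = n_rev + n_irr),
                 init = init, params = params, rates = rates),
            class = "bl_network")
}

#' @export
print.bl_network <- function(x, ...) {
  cat(sprintf("BL reaction network: M = %d, %d receptor conformations, %d reactions (%d reversible pairs + %d irreversible)\n",
              x$params$M, x$counts$n_species, x$counts$n_reactions,
              x$counts$n_reversible, x$counts$n_irreversible))
  invisible(x)
}

#' Export a reaction network as a plain-text listing
#'
#' Writes one reaction per line (reactants -> products, rate constant, law
#' kind) for audit.
#'
#' @param network a \code{\link{build_network}} object.
#' @param file path or connection; "" prints to the console.
#' @return invisibly, the character vector of lines.
#' @export
export_network <- function(network, file = "") {
  nm <- c(network$species$name, network$enzymes)
  side <- function(i1, i2) paste(stats::na.omit(nm[c(i1, i2)]), collapse = " + ")
  lines <- apply(network$reactions, 1L, function(r) {
    sprintf("%-14s %s -> %s  (c = %s)", r[["kind"]],
            side(as.integer(r[["r1"]]), as.integer(r[["r2"]])),
            side(as.integer(r[["p1"]]), as.integer(r[["p2"]])), r[["c"]])
  })
  writeLines(lines, con = file)
  invisible(lines)
}

# names of active conformations (enzyme-bound forms count with their
# conformation: CheB-bound intermediates are active, CheR-bound are not)
active_species <- function(network) {
  network$species$name[network$species$active]
}
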
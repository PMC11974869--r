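#' Path to the packaged signaling-network parameter file
#'
#' YAML description of the NKG2D / KIR2DL1 membrane-proximal signaling
#' network: species (compartment, diffusion coefficient, cluster
#' confinement, conserved moieties), rate constants with explicit unit and
#' volume classes, and the reaction list with kinetic-proofreading flags.
#'
#' @return file path of the YAML parameter file.
#' @export
nk_parameter_file <- function() {
  system.file("extdata", "nk_network.yaml", package = "nkrsig",
              mustWork = TRUE)
}

parse_reaction_string <- function(s) {
  sides <- strsplit(s, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("malformed reaction: ", s)
  split_side <- function(x) {
    parts <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  }
  list(reactants = split_side(sides[1]), products = split_side(sides[2]))
}

#' Build the signaling reaction network
#'
#' Reads the packaged parameter file and assembles the full reaction network
#' with per-reaction event propensities (1/s per reactant combination in a
#' chamber). Kinetic proofreading (KP) is modeled as irreversible
#' ligand-unbinding channels that reset the receptor complex to its basal
#' state, present alongside the ordinary state-preserving unbinding
#' reactions; dropping a KP flag removes the flagged reactions and changes
#' nothing else.
#'
#' @param kp_activating include the KP reset steps of NKG2D signaling?
#' @param kp_inhibitory include the KP reset steps of KIR2DL1 signaling?
#' @param geom an \code{nk_geometry}; propensities are computed for it.
#' @param file parameter file path (defaults to the packaged file).
#' @param rate_overrides named list of rate values replacing entries of the
#'   parameter file (units/volume classes unchanged).
#' @return An object of class \code{nk_network}: list with
#'   \describe{
#'     \item{species}{data.frame: name, compartment, D (um^2/s), confinement
#'       (\code{none}/\code{nkg2d}/\code{kir}), hop_rate (= D/l0^2, 1/s),
#'       phospho_vav (counts toward total pVav1).}
#'     \item{reactions}{data.frame: reaction string, rate name/value/unit,
#'       volume_class, propensity, kp flag, sector, bond.}
#'     \item{stoich}{species x reactions net stoichiometry matrix.}
#'     \item{reactant_idx}{list of reactant index vectors per reaction.}
#'     \item{moieties}{species x moiety composition matrix (receptor,
#'       ligand, kinase, Vav1, SHP-1 content of every species).}
#'     \item{counts}{default copy numbers from the parameter file.}
#'     \item{geom}{the geometry used.}
#'   }
#' @examples
#' net <- build_network()
#' nrow(net$reactions)
#' net_nokp <- build_network(kp_activating = FALSE, kp_inhibitory = FALSE)
#' sum(net_nokp$reactions$kp != "none")  # 0
#' @export
build_network <- function(kp_activating = TRUE, kp_inhibitory = TRUE,
                          geom = geometry_params(),
                          file = nk_parameter_file(),
                          rate_overrides = NULL) {
  spec <- yaml::read_yaml(file)
  for (nm in names(rate_overrides)) {
    if (is.null(spec$rates[[nm]])) stop("unknown rate name: ", nm)
    spec$rates[[nm]]$value <- rate_overrides[[nm]]
  }

  sp_names <- vapply(spec$species, `[[`, character(1), "name")
  species <- data.frame(
    name = sp_names,
    compartment = vapply(spec$species, `[[`, character(1), "compartment"),
    D = vapply(spec$species, `[[`, numeric(1), "D"),
    confinement = vapply(spec$species, `[[`, character(1), "confinement"),
    phospho_vav = vapply(spec$species, function(s)
      isTRUE(s$phospho_vav), logical(1)),
    stringsAsFactors = FALSE
  )
  species$hop_rate <- species$D / (geom$l0 * 1e-3)^2  # total hop rate, 1/s

  moiety_names <- sort(unique(unlist(lapply(spec$species, function(s)
    names(s$moieties)))))
  moieties <- matrix(0L, nrow = length(sp_names), ncol = length(moiety_names),
                     dimnames = list(sp_names, moiety_names))
  for (s in spec$species)
    for (m in names(s$moieties))
      moieties[s$name, m] <- as.integer(s$moieties[[m]])

  keep <- vapply(spec$reactions, function(r) {
    kp <- if (is.null(r$kp)) "none" else r$kp
    (kp != "activating" || kp_activating) &&
      (kp != "inhibitory" || kp_inhibitory)
  }, logical(1))
  rxns <- spec$reactions[keep]

  n_r <- length(rxns)
  reactant_idx <- vector("list", n_r)
  stoich <- matrix(0L, nrow = length(sp_names), ncol = n_r,
                   dimnames = list(sp_names, NULL))
  rows <- vector("list", n_r)
  for (j in seq_len(n_r)) {
    r <- rxns[[j]]
    parsed <- parse_reaction_string(r$reaction)
    unknown <- setdiff(c(parsed$reactants, parsed$products), sp_names)
    if (length(unknown))
      stop("parameter file references unknown species: ",
           paste(unknown, collapse = ", "))
    if (length(parsed$reactants) < 1L || length(parsed$reactants) > 2L)
      stop("reactions must have 1 or 2 reactants: ", r$reaction)
    reactant_idx[[j]] <- match(parsed$reactants, sp_names)
    for (x in parsed$reactants) stoich[x, j] <- stoich[x, j] - 1L
    for (x in parsed$products) stoich[x, j] <- stoich[x, j] + 1L

    rate_def <- spec$rates[[r$rate]]
    if (is.null(rate_def)) stop("unknown rate name: ", r$rate)
    vol <- r$volume  # NULL for unimolecular
    if (length(parsed$reactants) == 2L && is.null(vol))
      stop("bimolecular reaction lacks a volume class: ", r$reaction)
    rows[[j]] <- data.frame(
      reaction = r$reaction,
      rate_name = r$rate,
      rate = rate_def$value,
      unit = rate_def$unit,
      volume_class = if (is.null(vol)) NA_character_ else vol,
      propensity = rate_to_propensity(
        rate_def$value, rate_def$unit,
        if (is.null(vol)) NULL else vol, geom),
      kp = if (is.null(r$kp)) "none" else r$kp,
      sector = r$sector,
      bond = r$bond,
      stringsAsFactors = FALSE
    )
  }
  reactions <- do.call(rbind, rows)

  counts <- lapply(spec$counts, `[[`, "value")

  net <- list(species = species, reactions = reactions, stoich = stoich,
              reactant_idx = reactant_idx, moieties = moieties,
              counts = counts, geom = geom,
              kp_activating = kp_activating, kp_inhibitory = kp_inhibitory)
  class(net) <- "nk_network"

  viol <- moiety_violation(net)
  if (viol != 0)
    stop("parameter file is not moiety-conserving (max violation ", viol, ")")
  net
}

#' @export
print.nk_network <- function(x, ...) {
  cat(sprintf(
    "<nk_network> %d species, %d reactions (KP activating: %s, inhibitory: %s)\n",
    nrow(x$species), nrow(x$reactions),
    x$kp_activating, x$kp_inhibitory))
  invisible(x)
}

#' Audit moiety conservation of a network
#'
#' Every reaction must conserve each elementary moiety (receptor, ligand,
#' kinase, Vav1, SHP-1 content). Returns the maximum absolute net
#' stoichiometry of any moiety across all reactions; 0 means conserving.
#'
#' @param network an \code{nk_network}.
#' @return integer, maximum violation (0 if fully conserving).
#' @export
moiety_violation <- function(network) {
  net_change <- t(network$moieties) %*% network$stoich
  as.integer(max(abs(net_change)))
}

#' Default copy numbers for a simulated cell pair
#'
#' Copy numbers of every species in the simulation box. NKG2D (53),
#' KIR2DL1 (11686) and the HLA-C levels (low 4213 / high 11686) are the
#' printed values; SFK, Vav1 and SHP1 pools are the parameter file's
#' calibration constants.
#'
#' @param nkg2dl activating-ligand dose (molecules in the box, 20--400 in
#'   the study design; other non-negative integers allowed).
#' @param hlac \code{"low"}, \code{"high"}, or a non-negative count.
#' @param network an \code{nk_network} (for the default pools).
#' @return named integer vector over all network species (class
#'   \code{nk_counts}); species not listed start at zero.
#' @examples
#' cc <- cell_counts(nkg2dl = 400, hlac = "low")
#' cc[c("NKG2D", "KIR2DL1", "NKG2DL", "HLAC")]
#' @export
cell_counts <- function(nkg2dl = 20, hlac = c("low", "high"),
                        network = build_network()) {
  if (is.character(hlac)) {
    hlac <- match.arg(hlac)
    hlac_n <- if (hlac == "low") network$counts$HLAC_low
              else network$counts$HLAC_high
  } else {
    hlac_n <- hlac
  }
  stopifnot(nkg2dl >= 0, hlac_n >= 0)
  counts <- stats::setNames(integer(nrow(network$species)),
                            network$species$name)
  counts["NKG2D"] <- network$counts$NKG2D
  counts["KIR2DL1"] <- network$counts$KIR2DL1
  counts["NKG2DL"] <- as.integer(nkg2dl)
  counts["HLAC"] <- as.integer(hlac_n)
  counts["SFK"] <- network$counts$SFK
  counts["Vav1"] <- network$counts$Vav1
  counts["SHP1"] <- network$counts$SHP1
  class(counts) <- c("nk_counts", class(counts))
  counts
}

# species names whose copies carry a phosphorylated Vav1 moiety
pvav1_species <- function(network) {
  network$species$name[network$species$phospho_vav]
}
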
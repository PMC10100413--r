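# Trait tables: guild-specific trait inventories, fuzzy coding of
# species-level records into taxon-level affinity matrices, and the block
# schema that drives the mixed-type Gower dissimilarity.

#' Describe one trait block
#'
#' A block is either `"fuzzy"` (a set of `block.category` affinity columns
#' summing to 1 per taxon; single-level categorical traits are represented
#' the same way as one-hot affinities) or `"numeric"` (a single quantitative
#' column).
#'
#' @param name Block name (also the column prefix for fuzzy blocks).
#' @param type `"fuzzy"` or `"numeric"`.
#' @param levels Category levels for fuzzy blocks.
#' @param weight Nonnegative block weight used by
#'   [gower_dissimilarity()]; blocks are equally weighted by default.
#' @return A `trait_block` list.
#' @export
trait_block <- function(name, type = c("fuzzy", "numeric"), levels = NULL,
                        weight = 1) {
  type <- arg_match(type)
  if (type == "fuzzy" && length(levels) < 2) {
    abort("fuzzy blocks need at least 2 levels")
  }
  check_number(weight, "weight", lower = 0)
  structure(list(name = name, type = type, levels = levels, weight = weight),
            class = "trait_block")
}

block_columns <- function(block) {
  if (block$type == "numeric") block$name
  else paste(block$name, block$levels, sep = ".")
}

#' Built-in trait schema for a plankton guild
#'
#' Phytoplankton traits cover resource acquisition, reproduction and
#' predator defence: fuzzy cell-length (four size classes) and surface
#' area:volume blocks, a numeric organic-carbon ratio, and one-hot blocks
#' for trophy, nitrogen fixation, filament formation, mobility, coloniality
#' and silica use.  Zooplankton traits are fuzzy body length, trophic group,
#' feeding mode and reproductive mechanism.
#'
#' @param guild `"phyto"` or `"zoo"`.
#' @return A list of [trait_block()]s.
#' @export
guild_trait_schema <- function(guild = c("phyto", "zoo")) {
  guild <- arg_match(guild)
  if (guild == "phyto") {
    list(
      trait_block("cell_length", "fuzzy",
                  c("<=10", ">10-25", ">25-100", ">100")),
      trait_block("sa_vol_ratio", "fuzzy",
                  c("<0.5", ">0.5-1.0", ">1.0-5.0", ">5.0-10.0", ">10.0")),
      trait_block("organic_carbon_ratio", "numeric"),
      trait_block("trophy", "fuzzy", c("autotrophic", "mixotrophic")),
      trait_block("nitrogen_fixing", "fuzzy", c("yes", "no")),
      trait_block("filamentous", "fuzzy", c("yes", "no")),
      trait_block("mobility", "fuzzy", c("none", "flagellated", "rapheated")),
      trait_block("colonial", "fuzzy", c("colonial", "not_colonial")),
      trait_block("siliceous", "fuzzy", c("yes", "no")))
  } else {
    list(
      trait_block("body_length", "fuzzy",
                  c("<=0.3", ">0.3-0.9", ">0.9-1.5", ">1.5")),
      trait_block("trophic_group", "fuzzy",
                  c("herbivore", "omnivore", "carnivore", "omnicarnivore",
                    "omniherbivore")),
      trait_block("feeding_mode", "fuzzy",
                  c("bosmina_filtration", "chydorus_filtration",
                    "daphnia_filtration", "microfagous", "raptorial",
                    "sida_filtration", "suspension")),
      trait_block("reproductive_mechanism", "fuzzy",
                  c("sexual", "asexual", "cyclic_parthenogenesis")))
  }
}

new_fuzzy_trait_matrix <- function(tbl, schema) {
  tbl <- as_tibble(tbl)
  for (b in schema) {
    cols <- block_columns(b)
    miss <- setdiff(cols, names(tbl))
    if (length(miss) > 0) {
      abort(paste0("trait table lacks columns: ", toString(head(miss, 5))))
    }
    if (b$type == "fuzzy") {
      s <- rowSums(tbl[cols])
      bad <- is.finite(s) & abs(s - 1) > 1e-9
      if (any(bad)) {
        abort(sprintf("fuzzy block '%s' rows do not sum to 1", b$name))
      }
    }
  }
  structure(tbl, schema = schema,
            class = c("fuzzy_trait_matrix", class(tbl)))
}

trait_schema <- function(traits) {
  attr(traits, "schema") %||%
    abort("trait table carries no block schema; build it with fuzzy_code() or generate_trait_table()")
}

#' Generate a synthetic taxon-by-trait table
#'
#' Each taxon is treated as a small genus of member species; fuzzy-block
#' affinities are the fractions of member species falling in each category
#' (drawn from guild-level category prevalences), so rows sum to one by
#' construction.  Numeric traits are species means.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param guild `"phyto"` or `"zoo"`.
#' @param seed Integer seed.
#' @param taxa Optional taxon names (defaults to `<guild>_01`, ...).
#' @return A `fuzzy_trait_matrix` tibble with a `taxon` column and the
#'   guild's `block.category` / numeric columns.
#' @export
#' @examples
#' generate_trait_table(4, "zoo", seed = 1)
generate_trait_table <- function(n_taxa, guild = c("phyto", "zoo"), seed = 1,
                                 taxa = NULL) {
  check_count(n_taxa, "n_taxa", min = 2)
  guild <- arg_match(guild)
  schema <- guild_trait_schema(guild)
  taxa <- taxa %||% sprintf("%s_%02d", substr(guild, 1, 3), seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa)
  set.seed(child_seed(seed, paste0("trait_table/", guild)))
  out <- tibble(taxon = taxa)
  for (b in schema) {
    if (b$type == "numeric") {
      out[[b$name]] <- round(runif(n_taxa, 0.05, 0.95), 4)
    } else {
      k <- length(b$levels)
      prev <- rgamma(k, shape = 1) + 0.05   # guild-level category prevalence
      prev <- prev / sum(prev)
      aff <- t(vapply(seq_len(n_taxa), function(i) {
        n_sp <- 1 + stats::rpois(1, 2)      # member species per taxon
        tab <- tabulate(sample.int(k, n_sp, replace = TRUE, prob = prev), k)
        tab / n_sp
      }, numeric(k)))
      colnames(aff) <- block_columns(b)
      out <- dplyr::bind_cols(out, as_tibble(aff))
    }
  }
  new_fuzzy_trait_matrix(out, schema)
}

#' Fuzzy-code species-level trait records into a taxon-level matrix
#'
#' For a fuzzy block, a taxon's affinity to each category is the fraction of
#' its member species assigned to that category (so a monospecific taxon is
#' one-hot).  Numeric traits are averaged over member species.  Taxa whose
#' records carry no trait data at all are listed and excluded (attribute
#' `excluded`), never silently dropped.
#'
#' @param species_traits Data frame with a `taxon` column, one row per
#'   member species, categorical trait columns holding a single level and
#'   numeric trait columns.
#' @param schema List of [trait_block()]s; fuzzy blocks read the categorical
#'   column named `block$name`.
#' @return A `fuzzy_trait_matrix` tibble (one row per taxon).
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   taxon = c("g1", "g1", "g2"),
#'   cell_length = c("<=10", ">10-25", ">100"))
#' schema <- list(trait_block("cell_length", "fuzzy",
#'                            c("<=10", ">10-25", ">25-100", ">100")))
#' fuzzy_code(sp, schema)
fuzzy_code <- function(species_traits, schema) {
  species_traits <- as_tibble(species_traits)
  if (!"taxon" %in% names(species_traits)) {
    abort("`species_traits` needs a `taxon` column")
  }
  trait_cols <- vapply(schema, function(b) b$name, character(1))
  miss <- setdiff(trait_cols, names(species_traits))
  if (length(miss) > 0) {
    abort(paste0("species table lacks trait columns: ", toString(miss)))
  }
  has_data <- rowSums(!is.na(species_traits[trait_cols])) > 0
  by_taxon <- split(species_traits, species_traits$taxon)
  empty <- names(by_taxon)[!vapply(by_taxon, function(d) {
    any(rowSums(!is.na(d[trait_cols])) > 0)
  }, logical(1))]
  if (length(empty) > 0) {
    inform(paste0("excluding taxa with no trait data: ", toString(empty)))
    by_taxon <- by_taxon[setdiff(names(by_taxon), empty)]
  }
  if (length(by_taxon) == 0) abort("no taxa with trait data remain")

  rows <- purrr::map(by_taxon, function(d) {
    row <- tibble(taxon = d$taxon[1])
    for (b in schema) {
      v <- d[[b$name]]
      if (b$type == "numeric") {
        row[[b$name]] <- if (all(is.na(v))) NA_real_ else
          mean(as.numeric(v), na.rm = TRUE)
      } else {
        v <- v[!is.na(v)]
        cols <- block_columns(b)
        if (length(v) == 0) {
          row[cols] <- as.list(rep(NA_real_, length(cols)))
        } else {
          unknown <- setdiff(unique(v), b$levels)
          if (length(unknown) > 0) {
            abort(sprintf("unknown level(s) %s in trait '%s'",
                          toString(unknown), b$name))
          }
          tab <- table(factor(v, levels = b$levels))
          row[cols] <- as.list(as.numeric(tab) / length(v))
        }
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  res <- new_fuzzy_trait_matrix(out, schema)
  attr(res, "excluded") <- empty
  res
}
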
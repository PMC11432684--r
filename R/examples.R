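#' Example: psoriasis expression-hypothesis network
#'
#' A 17-node tripartite network encoding a published-style psoriasis
#' drug-response hypothesis: six retained seed genes (TNFAIP3, SHOC2, HTR2A,
#' MAP3K14, ERAP1, SPEN), seven miRNAs, and four lncRNAs (NEAT1, MAP3K1-2,
#' AKAP13-AS1, RP11-473M20.16). NEAT1 is taken as down-regulated in psoriatic
#' skin (RP11-473M20.16, weakly supported, is likewise set down), while
#' MAP3K1-2 and AKAP13-AS1 remain expressed. hsa-miR-485-3p and
#' hsa-miR-371a-3p receive lncRNA input only from the down-regulated lncRNAs,
#' so sponge-logic propagation leaves them active and represses their targets
#' TNFAIP3, SHOC2 and HTR2A; the remaining five miRNAs (placeholder names,
#' as only the two NEAT1-dependent miRNAs are identified in the narrative)
#' stay sponged by MAP3K1-2 or AKAP13-AS1, leaving MAP3K14, ERAP1 and SPEN
#' uninhibited.
#'
#' @return list with elements `network` (a [tripartite_network()]) and
#'   `assigned` (named character vector of lncRNA states to feed to
#'   [propagate_states()]).
#' @examples
#' ex <- psoriasis_axis_example()
#' states <- propagate_states(ex$network, ex$assigned)
#' states$mirna_states[c("hsa-miR-485-3p", "hsa-miR-371a-3p")]
#' @export
psoriasis_axis_example <- function() {
  seeds <- c("TNFAIP3", "SHOC2", "HTR2A", "MAP3K14", "ERAP1", "SPEN")
  mirnas <- c("hsa-miR-485-3p", "hsa-miR-371a-3p",
              sprintf("hsa-miR-sim-%d", 1:5))
  lncs <- c("NEAT1", "MAP3K1-2", "AKAP13-AS1", "RP11-473M20.16")
  nodes <- data.frame(
    id = c(seeds, mirnas, lncs),
    node_type = c(rep("seed", length(seeds)), rep("miRNA", length(mirnas)),
                  rep("lncRNA", length(lncs))),
    stringsAsFactors = FALSE
  )
  e <- function(a, b) data.frame(from = a, to = b, evidence_count = 1L,
                                 stringsAsFactors = FALSE)
  edges <- rbind(
    # lncRNA sponging edges
    e("NEAT1", "hsa-miR-485-3p"), e("NEAT1", "hsa-miR-371a-3p"),
    e("RP11-473M20.16", "hsa-miR-485-3p"),
    e("MAP3K1-2", "hsa-miR-sim-1"), e("MAP3K1-2", "hsa-miR-sim-2"),
    e("MAP3K1-2", "hsa-miR-sim-3"),
    e("AKAP13-AS1", "hsa-miR-sim-4"), e("AKAP13-AS1", "hsa-miR-sim-5"),
    # miRNA-target edges
    e("hsa-miR-485-3p", "TNFAIP3"), e("hsa-miR-485-3p", "HTR2A"),
    e("hsa-miR-371a-3p", "SHOC2"),
    e("hsa-miR-sim-1", "MAP3K14"), e("hsa-miR-sim-2", "ERAP1"),
    e("hsa-miR-sim-3", "SPEN"), e("hsa-miR-sim-4", "MAP3K14"),
    e("hsa-miR-sim-5", "ERAP1")
  )
  network <- tripartite_network(
    nodes, edges,
    seed_set = gene_set(seeds, role = "seed", label = "psoriasis example")
  )
  list(network = network,
       assigned = c(NEAT1 = "down", `RP11-473M20.16` = "down"))
}
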
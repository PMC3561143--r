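## Built-in pedigree shapes used as fixtures and simulation defaults.

.indiv <- function(id, father = NA, mother = NA, sex = 0, status = "unknown") {
  data.frame(id = id, father = father, mother = mother, sex = sex,
             status = status, stringsAsFactors = FALSE)
}

## A descent line of `depth` transmissions from founder couple (fa, mo),
## ending in a case; intermediate links get founder spouses.
.descentLine <- function(tag, fa, mo, depth) {
  rows <- list()
  for (g in seq_len(depth)) {
    id <- if (g == depth) paste0(tag, "_case") else paste0(tag, "_g", g)
    rows[[length(rows) + 1L]] <-
      .indiv(id, fa, mo, sex = 1,
             status = if (g == depth) "case" else "unknown")
    if (g < depth) {
      sp <- paste0(tag, "_sp", g)
      rows[[length(rows) + 1L]] <- .indiv(sp, sex = 2)
      fa <- id; mo <- sp
    }
  }
  do.call(rbind, rows)
}

#' Built-in pedigree templates
#'
#' Ready-made extended-pedigree shapes:
#' \describe{
#'   \item{`nuclear`}{two founders, two case children (siblings, d = 2).}
#'   \item{`cousins5`}{a founder couple with five children, each with one
#'     case child: five cases that are all mutual first cousins (every pair
#'     d = 4).  The default power-study shape.}
#'   \item{`ped5`, `ped9`, `ped10`}{approximations of extended high-risk
#'     pedigree shapes with 5, 9 and 10 cases connected by 17, 20 and 33
#'     meioses respectively (counting the transmissions in the minimal
#'     subpedigree joining the cases).  These are synthetic stand-ins, not
#'     reconstructions of any real family.}
#' }
#'
#' @param name template name.
#' @return a [Pedigree-class].
#' @examples
#' ped <- pedigreeTemplate("cousins5")
#' pairTable(ped)
#' @export
pedigreeTemplate <- function(name = c("nuclear", "cousins5", "ped5", "ped9",
                                      "ped10")) {
  name <- match.arg(name)
  top <- rbind(.indiv("F1", sex = 1), .indiv("F2", sex = 2))
  build <- function(...) Pedigree(rbind(top, ...), famId = name)
  switch(name,
    nuclear = build(.indiv("C1", "F1", "F2", 1, "case"),
                    .indiv("C2", "F1", "F2", 2, "case")),
    cousins5 = build(do.call(rbind, lapply(1:5, function(i) rbind(
      .indiv(paste0("U", i), "F1", "F2", 1),
      .indiv(paste0("S", i), sex = 2),
      .indiv(paste0("K", i), paste0("U", i), paste0("S", i), 2, "case"))))),
    ped5 = build(do.call(rbind, lapply(
      seq_len(5), function(i)
        .descentLine(paste0("L", i), "F1", "F2",
                     depth = c(3, 3, 3, 4, 4)[i])))),
    ped9 = {
      ## two depth-3 sib trios (5 meioses each), a depth-3 sib pair (4) and
      ## a depth-6 single (6): 20 connecting meioses over 9 cases
      sibship <- function(tag, nSibs) {
        ## parent two generations below the founders, then nSibs cases
        g1 <- paste0(tag, "_g1"); sp1 <- paste0(tag, "_sp1")
        g2 <- paste0(tag, "_g2"); sp2 <- paste0(tag, "_sp2")
        rbind(.indiv(g1, "F1", "F2", 1), .indiv(sp1, sex = 2),
              .indiv(g2, g1, sp1, 1), .indiv(sp2, sex = 2),
              do.call(rbind, lapply(seq_len(nSibs), function(i)
                .indiv(paste0(tag, "_case", i), g2, sp2, 2, "case"))))
      }
      pairb <- sibship("P", 2)
      build(sibship("T1", 3), sibship("T2", 3), pairb,
            .descentLine("S", "F1", "F2", depth = 6))
    },
    ped10 = {
      ## three depth-5 sib pairs (6 meioses each), one depth-4 sib pair (5)
      ## and two depth-5 singles (5 each): 33 meioses over 10 cases
      sibPairLine <- function(tag, depth) {
        inner <- .descentLine(tag, "F1", "F2", depth - 1)
        inner$status <- "unknown"
        last <- paste0(tag, "_case")   # repurpose line end as the parent
        sp <- paste0(tag, "_spL")
        rbind(inner, .indiv(sp, sex = 2),
              .indiv(paste0(tag, "_case1"), last, sp, 2, "case"),
              .indiv(paste0(tag, "_case2"), last, sp, 2, "case"))
      }
      build(sibPairLine("Q1", 5), sibPairLine("Q2", 5), sibPairLine("Q3", 5),
            sibPairLine("Q4", 4),
            .descentLine("R1", "F1", "F2", 5),
            .descentLine("R2", "F1", "F2", 5))
    })
}

#' Pedigree of n cases on disjoint descent lines from one founder couple
#'
#' Every case sits at the end of its own `depth`-transmission line from the
#' shared founder couple, so all case pairs are separated by `2 * depth`
#' meioses (depth 2 gives mutual first cousins, depth 5 the distant
#' cousin-style relationships typical of extended high-risk pedigrees).
#'
#' @param nCases number of cases (>= 2).
#' @param depth transmissions from the founder couple to each case.
#' @return a [Pedigree-class].
#' @export
linesPedigree <- function(nCases, depth) {
  if (nCases < 2L) stop("need at least 2 cases")
  top <- rbind(.indiv("F1", sex = 1), .indiv("F2", sex = 2))
  Pedigree(rbind(top, do.call(rbind, lapply(seq_len(nCases), function(i)
    .descentLine(paste0("L", i), "F1", "F2", depth)))),
    famId = sprintf("lines%dx%d", nCases, depth))
}

#' Minimal pedigree holding one pair of relatives d meioses apart
#'
#' Two descent lines of depth `ceiling(d/2)` and `floor(d/2)` from a common
#' founder couple, each ending in a case: `pairPedigree(2)` is a sib pair,
#' `pairPedigree(4)` first cousins.
#'
#' @param d meiosis count between the two cases (>= 2).
#' @return a [Pedigree-class] with exactly 2 cases.
#' @export
pairPedigree <- function(d) {
  d <- as.integer(d)
  if (d < 2L) stop("d must be at least 2 (siblings)")
  top <- rbind(.indiv("F1", sex = 1), .indiv("F2", sex = 2))
  Pedigree(rbind(top,
                 .descentLine("A", "F1", "F2", ceiling(d / 2)),
                 .descentLine("B", "F1", "F2", floor(d / 2))),
           famId = paste0("pair_d", d))
}
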
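"""msprime adapter for recombining IM simulations of a 2+2 sample.

Driven by the twotaxon R package. Two modes:

  branch    -- per replicate and block size, the integrated external branch
               lengths (tau * span, summed over blocks that carry at least one
               hetAB mutation) plus block counts; one TSV row per
               (replicate, block size).
  genotypes -- derived-allele counts of every biallelic site, one TSV row per
               site, for writing synthetic VCF fixtures.

Conventions match the R package: populations A and B split from AB `t`
generations ago; `ma` is the backwards-in-time per-generation rate at which
lineages move from A to B (population A receives migrants forwards in time);
samples are one diploid from each population (sample nodes 0,1 in A and 2,3
in B). Branch types on the unrooted 4-leaf genealogy: {a} or {a,b,b} -> a;
{b} or {a,a,b} -> b; {a,b} -> ab; {a,a}/{b,b} -> aa.
"""

import argparse
import sys

import msprime
import numpy as np


def branch_type(n_a, n_b):
    tot = n_a + n_b
    if tot >= 4:
        return -1
    if (n_a, n_b) == (1, 0) or (n_a, n_b) == (1, 2):
        return 0  # a
    if (n_a, n_b) == (0, 1) or (n_a, n_b) == (2, 1):
        return 1  # b
    if (n_a, n_b) == (1, 1):
        return 2  # ab
    return 3      # aa / bb


def build_demography(args):
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=args.na)
    dem.add_population(name="B", initial_size=args.nb)
    dem.add_population(name="AB", initial_size=args.nab)
    dem.add_population_split(time=args.t, derived=["A", "B"], ancestral="AB")
    # msprime's set_migration_rate(source, dest) is backwards in time:
    # lineages in `source` jump to `dest`
    if args.ma > 0:
        dem.set_migration_rate(source="A", dest="B", rate=args.ma)
    if args.mb > 0:
        dem.set_migration_rate(source="B", dest="A", rate=args.mb)
    dem.sort_events()
    return dem


def tree_type_lengths(tree, a_set, b_set):
    """Total branch length by type (a, b, ab, aa) for one marginal tree."""
    out = [0.0, 0.0, 0.0, 0.0]
    for u in tree.nodes():
        if tree.parent(u) == -1:
            continue
        samples = list(tree.samples(u))
        n_a = sum(1 for s in samples if s in a_set)
        n_b = sum(1 for s in samples if s in b_set)
        bt = branch_type(n_a, n_b)
        if bt >= 0:
            out[bt] += tree.branch_length(u)
    return out


def run_branch(args, dem, sizes, rng, fh):
    fh.write("rep\tblock_size\tsum_tau_a\tsum_tau_b\tn_cond\tn_blocks\n")
    a_set, b_set = {0, 1}, {2, 3}
    for rep in range(args.n_reps):
        ts = msprime.sim_ancestry(
            samples=[msprime.SampleSet(1, population="A", ploidy=2),
                     msprime.SampleSet(1, population="B", ploidy=2)],
            demography=dem, sequence_length=args.seq_len,
            recombination_rate=args.r, random_seed=args.seed + rep + 1)
        # per block size: integrated (tau * span) arrays by branch type
        acc = {s: np.zeros((3, int(np.ceil(args.seq_len / s)))) for s in sizes}
        for tree in ts.trees():
            ta, tb, tab, _ = tree_type_lengths(tree, a_set, b_set)
            left, right = tree.interval.left, tree.interval.right
            for s in sizes:
                i0 = int(left // s)
                i1 = int(np.ceil(right / s))
                for i in range(i0, i1):
                    ov = min(right, (i + 1) * s) - max(left, i * s)
                    if ov <= 0:
                        continue
                    acc[s][0, i] += ta * ov
                    acc[s][1, i] += tb * ov
                    acc[s][2, i] += tab * ov
        for s in sizes:
            k_ab = rng.poisson(args.mu * acc[s][2])
            cond = k_ab >= 1
            fh.write("%d\t%d\t%.10g\t%.10g\t%d\t%d\n" % (
                rep, s, acc[s][0, cond].sum(), acc[s][1, cond].sum(),
                int(cond.sum()), acc[s].shape[1]))


def run_genotypes(args, dem, fh):
    fh.write("rep\tpos\tg_a\tg_b\n")
    for rep in range(args.n_reps):
        ts = msprime.sim_ancestry(
            samples=[msprime.SampleSet(1, population="A", ploidy=2),
                     msprime.SampleSet(1, population="B", ploidy=2)],
            demography=dem, sequence_length=args.seq_len,
            recombination_rate=args.r, random_seed=args.seed + rep + 1)
        mts = msprime.sim_mutations(ts, rate=args.mu,
                                    random_seed=args.seed + rep + 1)
        for var in mts.variants():
            if len(var.alleles) != 2:
                continue  # keep strictly biallelic sites
            g = var.genotypes
            fh.write("%d\t%d\t%d\t%d\n" % (
                rep, int(var.site.position) + 1, g[0] + g[1], g[2] + g[3]))


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--mode", choices=["branch", "genotypes"], required=True)
    for name in ["na", "nb", "nab", "t", "ma", "mb", "mu", "r"]:
        ap.add_argument("--" + name, type=float, required=(name != "r"),
                        default=0.0)
    ap.add_argument("--seq-len", type=int, required=True)
    ap.add_argument("--n-reps", type=int, required=True)
    ap.add_argument("--block-sizes", type=str, default="")
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", type=str, default="-")
    args = ap.parse_args()

    dem = build_demography(args)
    rng = np.random.default_rng(args.seed)
    fh = sys.stdout if args.out == "-" else open(args.out, "w")
    if args.mode == "branch":
        if not args.block_sizes:
            raise SystemExit("--block-sizes required in branch mode")
        sizes = [int(x) for x in args.block_sizes.split(",")]
        run_branch(args, dem, sizes, rng, fh)
    else:
        run_genotypes(args, dem, fh)
    if fh is not sys.stdout:
        fh.close()


if __name__ == "__main__":
    main()
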
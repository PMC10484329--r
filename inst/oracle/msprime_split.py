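"""Independent two-deme split oracle: msprime genealogies, one uniform
mutation per locus, derived-allele counts per deme written as TSV."""
import sys
import msprime
import numpy as np

def main(n1, n2, t_split_4n, n_loci, seed, out):
    N = 500.0  # diploid deme size; 4N = 2000 generations
    t_gen = t_split_4n * 4 * N
    demography = msprime.Demography()
    demography.add_population(name="deme1", initial_size=N)
    demography.add_population(name="deme2", initial_size=N)
    demography.add_population(name="anc", initial_size=N)
    demography.add_population_split(time=t_gen, derived=["deme1", "deme2"],
                                    ancestral="anc")
    rng = np.random.default_rng(seed)
    rows = []
    # ms time scale: diploid demes of size N, pair coalescence 1/(2N);
    # haploid genomes sampled from the diploid-scaled model
    samples = [msprime.SampleSet(n1, population="deme1", ploidy=1),
               msprime.SampleSet(n2, population="deme2", ploidy=1)]
    reps = msprime.sim_ancestry(
        samples=samples, ploidy=2,
        demography=demography, num_replicates=n_loci, random_seed=seed)
    for ts in reps:
        tree = ts.first()
        nodes = [u for u in tree.nodes() if tree.parent(u) != -1]
        lens = np.array([tree.branch_length(u) for u in nodes])
        hit = nodes[rng.choice(len(nodes), p=lens / lens.sum())]
        below = list(tree.samples(hit))
        d1 = sum(1 for s in below if ts.node(s).population == 0)
        d2 = len(below) - d1
        rows.append((d1, d2))
    with open(out, "w") as fh:
        fh.write("d1\td2\n")
        for d1, d2 in rows:
            fh.write(f"{d1}\t{d2}\n")

if __name__ == "__main__":
    a = sys.argv[1:]
    main(int(a[0]), int(a[1]), float(a[2]), int(a[3]), int(a[4]), a[5])
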
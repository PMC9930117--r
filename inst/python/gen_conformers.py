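"""Seeded conformer ensemble generation.

Reads a SMILES file ("SMILES id" per line), embeds up to --max-conformers
distance-geometry conformers per molecule (ETKDG, seeded), minimises them
with MMFF94, keeps those within --energy-window kcal/mol of each molecule's
minimum after RMS deduplication, and writes an SDF whose records carry the
molecule id in the title and the relative energy in the "energy_rel"
property.  Deterministic given --seed.
"""
import argparse
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("smiles_file")
    ap.add_argument("out_sdf")
    ap.add_argument("--max-conformers", type=int, default=255)
    ap.add_argument("--energy-window", type=float, default=20.0)
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--rms-threshold", type=float, default=0.35)
    args = ap.parse_args()

    writer = Chem.SDWriter(args.out_sdf)
    failures = []
    for line in open(args.smiles_file):
        parts = line.split()
        if not parts:
            continue
        smi, mid = parts[0], parts[1] if len(parts) > 1 else parts[0]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            failures.append(mid)
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = args.seed
        params.pruneRmsThresh = args.rms_threshold
        params.numThreads = 1
        n_target = min(args.max_conformers,
                       max(8, 3 ** AllChem.CalcNumRotatableBonds(mol)))
        cids = AllChem.EmbedMultipleConfs(molh, numConfs=n_target,
                                          params=params)
        if len(cids) == 0:
            failures.append(mid)
            continue
        res = AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=2000)
        energies = []
        for cid, (converged, energy) in zip(cids, res):
            energies.append((cid, energy if energy == energy else None))
        valid = [(c, e) for c, e in energies if e is not None]
        if not valid:
            valid = [(c, 0.0) for c, _ in energies]
        emin = min(e for _, e in valid)
        kept = [(c, e - emin) for c, e in valid
                if e - emin <= args.energy_window]
        kept.sort(key=lambda t: t[1])
        kept = kept[: args.max_conformers]
        for c, erel in kept:
            molh.SetProp("_Name", mid)
            molh.SetProp("energy_rel", "%.6f" % erel)
            writer.write(molh, confId=c)
    writer.close()
    if failures:
        sys.stderr.write("embedding failed: " + ",".join(failures) + "\n")
        sys.exit(3)


if __name__ == "__main__":
    main()
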
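"""Deterministic 3D embedding: ETKDG distance geometry with an explicit
random seed, followed by a short MMFF relaxation (both deterministic).

Usage: python embed3d.py <in.smi> <out.sdf> <seed>
  in.smi: one record per line, "SMILES<TAB>id"
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(src, dst, seed):
    writer = Chem.SDWriter(dst)
    with open(src) as fh:
        for ln, line in enumerate(fh, 1):
            line = line.strip()
            if not line:
                continue
            parts = line.split("\t")
            smi = parts[0]
            name = parts[1] if len(parts) > 1 else "mol%d" % ln
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                sys.stderr.write("record %d (%s): unparsable SMILES\n"
                                 % (ln, name))
                return 2
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            if AllChem.EmbedMolecule(mol, params) != 0:
                sys.stderr.write("record %d (%s): embedding failed\n"
                                 % (ln, name))
                return 3
            try:
                AllChem.MMFFOptimizeMolecule(mol, maxIters=200)
            except Exception:
                pass  # leave the raw embedding; the caller minimizes anyway
            mol.SetProp("_Name", name)
            writer.write(mol)
    writer.close()
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1], sys.argv[2], int(sys.argv[3])))
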
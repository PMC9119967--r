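# Independent reference parser for the featurization oracle tests.
# Usage:
#   python rdkit_reference.py smiles <file-with-one-smiles-per-line>
#   python rdkit_reference.py seq <file-with-one-sequence-per-line>
# Prints JSON to stdout.
import sys, json
from rdkit import Chem
from rdkit.Chem.Scaffolds import MurckoScaffold

mode, path = sys.argv[1], sys.argv[2]
lines = [l.strip() for l in open(path) if l.strip()]
out = []

if mode == "smiles":
    for smi in lines:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append(None)
            continue
        atoms = []
        for a in mol.GetAtoms():
            atoms.append([
                a.GetAtomicNum(), str(a.GetChiralTag()), a.GetDegree(),
                a.GetFormalCharge(), a.GetTotalNumHs(),
                a.GetNumRadicalElectrons(), str(a.GetHybridization()),
                int(a.GetIsAromatic()), int(a.IsInRing()),
            ])
        bonds = []
        for b in mol.GetBonds():
            bonds.append([
                b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                str(b.GetBondType()), str(b.GetStereo()),
                int(b.GetIsConjugated()),
            ])
        sc = MurckoScaffold.GetScaffoldForMol(mol)
        out.append({"n_atoms": mol.GetNumAtoms(), "n_bonds": mol.GetNumBonds(),
                    "atoms": atoms, "bonds": bonds,
                    "scaffold_n_atoms": sc.GetNumAtoms()})
elif mode == "seq":
    for seq in lines:
        mol = Chem.MolFromSequence(seq)
        if mol is None:
            out.append(None)
            continue
        counts = {}
        for a in mol.GetAtoms():
            counts[a.GetSymbol()] = counts.get(a.GetSymbol(), 0) + 1
        out.append({"n_atoms": mol.GetNumAtoms(), "n_bonds": mol.GetNumBonds(),
                    "counts": counts})
else:
    raise SystemExit("unknown mode")

print(json.dumps(out))
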
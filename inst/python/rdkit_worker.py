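"""MMFF94 backend worker for turnscout.

Thin command-line wrapper around RDKit used by the R package for the three
chemistry services it buys rather than builds: SMILES parsing, ETKDG
distance-geometry embedding, and MMFF94 minimization/energy evaluation.
All conformational-search logic lives on the R side; this script only maps
SDF records to minimized SDF records.

Protocol: every output SDF record carries the properties
  E_kcal_mol  -- MMFF94 energy after any minimization
  converged   -- 1/0 flag from the minimizer
Atom order is preserved for SDF input and is the RDKit AddHs order for
SMILES input, so the caller can rely on stable atom indexing.
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def fail(msg, code=2):
    sys.stderr.write("rdkit_worker: " + msg + "\n")
    sys.exit(code)


def mol_from_smiles(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        fail("SMILES parse failure: %r" % smiles)
    try:
        mol = Chem.AddHs(mol)
    except Exception as exc:  # pragma: no cover - rdkit raises rarely here
        fail("hydrogen materialization failed: %s" % exc)
    return mol


def read_sdf(path):
    supp = Chem.SDMolSupplier(path, removeHs=False, sanitize=True)
    mols = [m for m in supp]
    if not mols or any(m is None for m in mols):
        fail("SDF parse failure in %s" % path)
    return mols


def mmff_minimize(mol, conf_id=-1, max_iters=20000):
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        fail("MMFF94 cannot type this molecule")
    ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=conf_id)
    not_converged = ff.Minimize(maxIts=max_iters)
    return ff.CalcEnergy(), int(not_converged == 0)


def mmff_energy(mol, conf_id=-1):
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is None:
        fail("MMFF94 cannot type this molecule")
    ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=conf_id)
    return ff.CalcEnergy()


def write_mols(mols, path):
    writer = Chem.SDWriter(path)
    writer.SetKekulize(True)
    for m in mols:
        writer.write(m)
    writer.close()


def cmd_prepare(args):
    """SMILES -> explicit-H molecular graph with one embedded, minimized
    conformer, written as a single SDF record."""
    mol = mol_from_smiles(args.smiles)
    params = AllChem.ETKDGv3()
    params.randomSeed = args.seed
    params.useRandomCoords = False
    if AllChem.EmbedMolecule(mol, params) != 0:
        # bounded retries with perturbed seeds, then random-coordinate mode
        ok = False
        for k in range(1, 6):
            params.randomSeed = args.seed + k
            if AllChem.EmbedMolecule(mol, params) == 0:
                ok = True
                break
        if not ok:
            params.useRandomCoords = True
            if AllChem.EmbedMolecule(mol, params) != 0:
                fail("3D embedding failed after retries")
    energy, conv = mmff_minimize(mol)
    mol.SetProp("E_kcal_mol", repr(energy))
    mol.SetProp("converged", str(conv))
    Chem.AssignStereochemistryFrom3D(mol)
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    stereo = [
        "%d:%s" % (a.GetIdx() + 1, a.GetProp("_CIPCode"))
        for a in mol.GetAtoms()
        if a.HasProp("_CIPCode")
    ]
    mol.SetProp("stereo_descriptors", " ".join(stereo))
    write_mols([mol], args.out)


def cmd_embed(args):
    """SMILES -> n independently embedded (and optionally minimized)
    conformers, one SDF record each, seeds seed, seed+1, ..."""
    mol = mol_from_smiles(args.smiles)
    out = []
    for i in range(args.n):
        m = Chem.Mol(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = args.seed + i
        if AllChem.EmbedMolecule(m, params) != 0:
            continue
        if args.minimize:
            energy, conv = mmff_minimize(m)
        else:
            energy, conv = mmff_energy(m), 1
        m.SetProp("E_kcal_mol", repr(energy))
        m.SetProp("converged", str(conv))
        m.SetProp("start_index", str(i))
        out.append(m)
    if not out:
        fail("no start could be embedded")
    write_mols(out, args.out)


def cmd_minimize(args):
    mols = read_sdf(args.inp)
    for m in mols:
        energy, conv = mmff_minimize(m, max_iters=args.max_iters)
        m.SetProp("E_kcal_mol", repr(energy))
        m.SetProp("converged", str(conv))
    write_mols(mols, args.out)


def cmd_energy(args):
    mols = read_sdf(args.inp)
    for m in mols:
        sys.stdout.write(repr(mmff_energy(m)) + "\n")


def main(argv=None):
    parser = argparse.ArgumentParser(prog="rdkit_worker")
    sub = parser.add_subparsers(dest="command", required=True)

    p = sub.add_parser("prepare")
    p.add_argument("--smiles", required=True)
    p.add_argument("--seed", type=int, default=1234)
    p.add_argument("--out", required=True)
    p.set_defaults(func=cmd_prepare)

    p = sub.add_parser("embed")
    p.add_argument("--smiles", required=True)
    p.add_argument("--n", type=int, required=True)
    p.add_argument("--seed", type=int, default=1234)
    p.add_argument("--minimize", action="store_true")
    p.add_argument("--out", required=True)
    p.set_defaults(func=cmd_embed)

    p = sub.add_parser("minimize")
    p.add_argument("--in", dest="inp", required=True)
    p.add_argument("--out", required=True)
    p.add_argument("--max-iters", dest="max_iters", type=int, default=20000)
    p.set_defaults(func=cmd_minimize)

    p = sub.add_parser("energy")
    p.add_argument("--in", dest="inp", required=True)
    p.set_defaults(func=cmd_energy)

    args = parser.parse_args(argv)
    args.func(args)


if __name__ == "__main__":
    main()
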
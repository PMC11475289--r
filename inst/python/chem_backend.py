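#!/usr/bin/env python
"""RDKit worker for the rxnvec R package.

Serves batched cheminformatics primitives over a line-delimited JSON protocol
on a localhost socket. The R side starts one worker per session and sends one
request object per line: {"id": n, "op": str, "args": {...}}; the worker
replies {"id": n, "ok": true, "result": ...} or {"id": n, "ok": false,
"error": str}. The worker exits when its parent R process goes away, on
"shutdown", or after a long idle period.
"""

import json
import os
import socket
import sys
import threading
import time

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, Crippen, Lipinski, rdMolDescriptors
from rdkit.Chem.EnumerateStereoisomers import (
    EnumerateStereoisomers,
    StereoEnumerationOptions,
)

RDLogger.DisableLog("rdApp.*")

IDLE_TIMEOUT = 1800  # seconds without a client before giving up


def _mol_from_smiles(smi):
    return Chem.MolFromSmiles(smi)


def op_ping(args):
    return "pong"


def _atom_record(atom, ring_info):
    return {
        "element": atom.GetSymbol(),
        "arom": atom.GetIsAromatic(),
        "charge": atom.GetFormalCharge(),
        "nh": atom.GetTotalNumHs(),
        "map": atom.GetAtomMapNum(),
        "ring": ring_info.NumAtomRings(atom.GetIdx()),
    }


def op_parse(args):
    """SMILES -> graph records with kekulized bond orders and aromatic flags."""
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparseable SMILES: %s" % smi})
            continue
        kek = Chem.Mol(mol)
        try:
            Chem.Kekulize(kek, clearAromaticFlags=False)
        except Exception as exc:  # pragma: no cover - sanitised mols kekulize
            out.append({"ok": False, "error": "kekulization failed: %s" % exc})
            continue
        ring_info = mol.GetRingInfo()
        atoms = [_atom_record(a, ring_info) for a in mol.GetAtoms()]
        bonds = []
        for b in kek.GetBonds():
            bonds.append(
                {
                    "a": b.GetBeginAtomIdx() + 1,
                    "b": b.GetEndAtomIdx() + 1,
                    "order": int(b.GetBondTypeAsDouble()),
                    "arom": mol.GetBondBetweenAtoms(
                        b.GetBeginAtomIdx(), b.GetEndAtomIdx()
                    ).GetIsAromatic(),
                }
            )
        plain = Chem.Mol(mol)
        for a in plain.GetAtoms():
            a.SetAtomMapNum(0)
        out.append(
            {
                "ok": True,
                "canonical": Chem.MolToSmiles(plain),
                "atoms": atoms,
                "bonds": bonds,
            }
        )
    return out


_BOND_ORDERS = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE, 3: Chem.BondType.TRIPLE}


def op_build(args):
    """Graph records (kekulized orders) -> sanitised canonical SMILES."""
    out = []
    for rec in args["mols"]:
        try:
            rw = Chem.RWMol()
            for at in rec["atoms"]:
                a = Chem.Atom(at["element"])
                a.SetFormalCharge(int(at.get("charge", 0)))
                a.SetNoImplicit(False)
                rw.AddAtom(a)
            for bd in rec.get("bonds", []):
                rw.AddBond(int(bd["a"]) - 1, int(bd["b"]) - 1, _BOND_ORDERS[int(bd["order"])])
            mol = rw.GetMol()
            Chem.SanitizeMol(mol)
            out.append({"ok": True, "smiles": Chem.MolToSmiles(mol)})
        except Exception as exc:
            out.append({"ok": False, "error": str(exc)})
    return out


def op_canonical(args):
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
        else:
            for a in mol.GetAtoms():
                a.SetAtomMapNum(0)
            out.append(Chem.MolToSmiles(mol))
    return out


def op_morgan(args):
    """Binary Morgan fingerprints: lists of on-bit indices (0-based)."""
    radius = int(args.get("radius", 2))
    nbits = int(args.get("nbits", 1024))
    feat = bool(args.get("features", False))
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(
            mol, radius, nBits=nbits, useFeatures=feat
        )
        out.append(list(fp.GetOnBits()))
    return out


def op_morgan_counts(args):
    """Hashed count fingerprints (FeatMorgan when features=true): sparse idx/cnt."""
    radius = int(args.get("radius", 2))
    nbits = int(args.get("nbits", 1024))
    feat = bool(args.get("features", True))
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        fp = rdMolDescriptors.GetHashedMorganFingerprint(
            mol, radius, nBits=nbits, useFeatures=feat
        )
        nz = fp.GetNonzeroElements()
        out.append({"idx": [int(k) for k in nz.keys()], "cnt": [int(v) for v in nz.values()]})
    return out


def op_smarts(args):
    """Substructure match counts: one row per molecule, one column per pattern."""
    pats = []
    for p in args["patterns"]:
        q = Chem.MolFromSmarts(p)
        if q is None:
            raise ValueError("invalid SMARTS: %s" % p)
        pats.append(q)
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        out.append([len(mol.GetSubstructMatches(q)) for q in pats])
    return out


def op_descriptors(args):
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        out.append(
            {
                "mw": Descriptors.MolWt(mol),
                "logp": Crippen.MolLogP(mol),
                "hbd": Lipinski.NumHDonors(mol),
                "hba": Lipinski.NumHAcceptors(mol),
            }
        )
    return out


def op_stereo_enum(args):
    cap = int(args.get("cap", 32))
    opts = StereoEnumerationOptions(onlyUnassigned=True, maxIsomers=cap, unique=True)
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        isomers = [Chem.MolToSmiles(m) for m in EnumerateStereoisomers(mol, options=opts)]
        out.append(sorted(isomers))
    return out


def op_unassigned_stereocentres(args):
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        centres = Chem.FindMolChiralCenters(
            mol, includeUnassigned=True, useLegacyImplementation=False
        )
        out.append(sum(1 for _, lab in centres if lab == "?"))
    return out


def op_random_smiles(args):
    """Equivalent randomised SMILES strings (atom-renumbering invariance tests)."""
    n = int(args.get("n", 1))
    seed = int(args.get("seed", 42))
    out = []
    for smi in args["smiles"]:
        mol = _mol_from_smiles(smi)
        if mol is None:
            out.append(None)
            continue
        import random

        rng = random.Random(seed)
        variants = []
        for _ in range(n):
            order = list(range(mol.GetNumAtoms()))
            rng.shuffle(order)
            shuffled = Chem.RenumberAtoms(mol, order)
            variants.append(Chem.MolToSmiles(shuffled, canonical=False))
        out.append(variants)
    return out


def op_read_sdf(args):
    supplier = Chem.SDMolSupplier(args["path"])
    out = []
    for mol in supplier:
        if mol is None:
            out.append(None)
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        out.append({"smiles": Chem.MolToSmiles(mol), "name": name})
    return out


def op_mcs(args):
    """Maximum common substructure atom correspondence between two molecules."""
    from rdkit.Chem import rdFMCS

    out = []
    for pair in args["pairs"]:
        ma = _mol_from_smiles(pair["a"])
        mb = _mol_from_smiles(pair["b"])
        if ma is None or mb is None:
            out.append(None)
            continue
        res = rdFMCS.FindMCS(
            [ma, mb],
            bondCompare=rdFMCS.BondCompare.CompareOrderExact,
            atomCompare=rdFMCS.AtomCompare.CompareElements,
            timeout=10,
        )
        if res.canceled or res.numAtoms == 0:
            out.append({"a_matches": [], "b_matches": []})
            continue
        patt = Chem.MolFromSmarts(res.smartsString)
        am = ma.GetSubstructMatches(patt, uniquify=False, maxMatches=64)
        bm = mb.GetSubstructMatches(patt, uniquify=False, maxMatches=64)
        out.append(
            {
                "a_matches": [[i + 1 for i in m] for m in am],
                "b_matches": [[i + 1 for i in m] for m in bm],
            }
        )
    return out


OPS = {
    "ping": op_ping,
    "parse": op_parse,
    "build": op_build,
    "canonical": op_canonical,
    "morgan": op_morgan,
    "morgan_counts": op_morgan_counts,
    "smarts": op_smarts,
    "descriptors": op_descriptors,
    "stereo_enum": op_stereo_enum,
    "unassigned_stereocentres": op_unassigned_stereocentres,
    "random_smiles": op_random_smiles,
    "read_sdf": op_read_sdf,
    "mcs": op_mcs,
}


def _watch_parent(ppid):
    while True:
        time.sleep(5)
        if os.getppid() != ppid:
            os._exit(0)


def serve(portfile):
    ppid = os.getppid()
    threading.Thread(target=_watch_parent, args=(ppid,), daemon=True).start()
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    srv.settimeout(IDLE_TIMEOUT)
    with open(portfile + ".tmp", "w") as fh:
        fh.write(str(srv.getsockname()[1]))
    os.replace(portfile + ".tmp", portfile)
    while True:
        try:
            conn, _ = srv.accept()
        except socket.timeout:
            return
        fh = conn.makefile("rwb")
        for line in fh:
            if not line.strip():
                continue
            try:
                req = json.loads(line)
            except ValueError:
                continue
            if req.get("op") == "shutdown":
                return
            try:
                result = OPS[req["op"]](req.get("args", {}))
                resp = {"id": req.get("id"), "ok": True, "result": result}
            except Exception as exc:
                resp = {"id": req.get("id"), "ok": False, "error": str(exc)}
            fh.write((json.dumps(resp) + "\n").encode())
            fh.flush()
        fh.close()
        conn.close()


def main():
    if len(sys.argv) >= 3 and sys.argv[1] == "--portfile":
        serve(sys.argv[2])
    else:
        sys.stderr.write("usage: chem_backend.py --portfile FILE\n")
        sys.exit(2)


if __name__ == "__main__":
    main()
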
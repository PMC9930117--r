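// Fragment enumeration and hashing for the sparse 2D fingerprints.
//
// All sparse fingerprints map canonical fragment strings onto a 32-bit bit
// space with FNV-1a.  Bits are returned as doubles because R has no native
// unsigned 32-bit integer type; every value is an exact integer < 2^32.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint32_t fnv1a(const std::string& s) {
  uint32_t h = 2166136261u;
  for (unsigned char c : s) {
    h ^= static_cast<uint32_t>(c);
    h *= 16777619u;
  }
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_fnv1a(CharacterVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = static_cast<double>(fnv1a(std::string(x[i])));
  return out;
}

struct Graph {
  int n;
  std::vector<std::string> atok;            // atom type token per atom
  std::vector<std::vector<int>> nbr;        // adjacency (atom indices)
  std::vector<std::vector<std::string>> btok; // bond token parallel to nbr
};

static Graph build_graph(CharacterVector atom_tokens,
                         IntegerVector bi, IntegerVector bj,
                         CharacterVector bond_tokens) {
  Graph g;
  g.n = atom_tokens.size();
  g.atok.resize(g.n);
  for (int i = 0; i < g.n; ++i) g.atok[i] = std::string(atom_tokens[i]);
  g.nbr.resize(g.n);
  g.btok.resize(g.n);
  for (R_xlen_t e = 0; e < bi.size(); ++e) {
    int a = bi[e] - 1, b = bj[e] - 1;
    std::string t(bond_tokens[e]);
    g.nbr[a].push_back(b); g.btok[a].push_back(t);
    g.nbr[b].push_back(a); g.btok[b].push_back(t);
  }
  return g;
}

static NumericVector set_to_bits(const std::set<uint32_t>& bits) {
  NumericVector out(bits.size());
  R_xlen_t k = 0;
  for (uint32_t b : bits) out[k++] = static_cast<double>(b);
  return out;
}

// Radial (circular/ECFP-like) fingerprint.  Iterative environment codes: the
// radius-0 code hashes the atom type token; the radius-r code hashes the
// radius, the centre's previous code and the sorted multiset of
// (bond token, neighbour previous code).  A code is emitted only while the
// r-bond neighbourhood is still growing, so a lone atom yields exactly one
// bit and an r-regular small molecule one bit per informative radius.
// [[Rcpp::export]]
NumericVector cpp_radial_bits(CharacterVector atom_tokens,
                              IntegerVector bond_i, IntegerVector bond_j,
                              CharacterVector bond_tokens,
                              int iterations) {
  Graph g = build_graph(atom_tokens, bond_i, bond_j, bond_tokens);
  std::set<uint32_t> bits;
  if (g.n == 0) return NumericVector(0);

  std::vector<uint32_t> code(g.n), prev(g.n);
  // BFS distances for neighbourhood-growth bookkeeping
  std::vector<std::vector<int>> dist(g.n, std::vector<int>(g.n, -1));
  for (int s = 0; s < g.n; ++s) {
    std::vector<int> q{s};
    dist[s][s] = 0;
    for (size_t qi = 0; qi < q.size(); ++qi) {
      int u = q[qi];
      for (int v : g.nbr[u])
        if (dist[s][v] < 0) { dist[s][v] = dist[s][u] + 1; q.push_back(v); }
    }
  }
  auto nbhd_size = [&](int s, int r) {
    int c = 0;
    for (int v = 0; v < g.n; ++v)
      if (dist[s][v] >= 0 && dist[s][v] <= r) ++c;
    return c;
  };

  for (int a = 0; a < g.n; ++a) {
    code[a] = fnv1a(g.atok[a]);
    bits.insert(code[a]);
  }
  for (int r = 1; r <= iterations; ++r) {
    prev = code;
    for (int a = 0; a < g.n; ++a) {
      std::vector<std::string> parts;
      for (size_t k = 0; k < g.nbr[a].size(); ++k)
        parts.push_back(g.btok[a][k] + ":" + std::to_string(prev[g.nbr[a][k]]));
      std::sort(parts.begin(), parts.end());
      std::string s = std::to_string(r) + "|" + std::to_string(prev[a]);
      for (const auto& p : parts) s += "|" + p;
      code[a] = fnv1a(s);
      if (nbhd_size(a, r) > nbhd_size(a, r - 1)) bits.insert(code[a]);
    }
  }
  return set_to_bits(bits);
}

// Dendritic fingerprint: every connected fragment that is a simple path or a
// tree with exactly one branching vertex, with at most `max_bonds` bonds.
// Fragments are serialised canonically (paths: lexicographic minimum of the
// two directions; stars: centre token plus sorted leg strings) and hashed.

static std::string path_string(const Graph& g, const std::vector<int>& atoms,
                               const std::vector<std::string>& bonds) {
  // forward
  std::string f = g.atok[atoms[0]];
  for (size_t k = 0; k < bonds.size(); ++k)
    f += bonds[k] + g.atok[atoms[k + 1]];
  // reverse
  std::string r = g.atok[atoms.back()];
  for (size_t k = bonds.size(); k-- > 0;)
    r += bonds[k] + g.atok[atoms[k]];
  return std::min(f, r);
}

static void enumerate_paths(const Graph& g, int max_bonds,
                            std::vector<int>& atoms,
                            std::vector<std::string>& bonds,
                            std::vector<bool>& used,
                            std::set<uint32_t>& bits) {
  int last = atoms.back();
  if (!bonds.empty()) bits.insert(fnv1a("P|" + path_string(g, atoms, bonds)));
  if ((int)bonds.size() >= max_bonds) return;
  for (size_t k = 0; k < g.nbr[last].size(); ++k) {
    int v = g.nbr[last][k];
    if (used[v]) continue;
    used[v] = true;
    atoms.push_back(v);
    bonds.push_back(g.btok[last][k]);
    enumerate_paths(g, max_bonds, atoms, bonds, used, bits);
    bonds.pop_back();
    atoms.pop_back();
    used[v] = false;
  }
}

// legs from a centre: simple paths rooted at the centre, serialised outward
struct Leg {
  std::vector<int> atoms;   // excluding the centre
  std::string str;          // bond+atom token string, outward
};

static void collect_legs(const Graph& g, int centre, int max_len,
                         std::vector<int>& atoms, std::string& str,
                         std::vector<bool>& used, std::vector<Leg>& legs) {
  int last = atoms.empty() ? centre : atoms.back();
  if (!atoms.empty()) legs.push_back({atoms, str});
  if ((int)atoms.size() >= max_len) return;
  for (size_t k = 0; k < g.nbr[last].size(); ++k) {
    int v = g.nbr[last][k];
    if (v == centre || used[v]) continue;
    used[v] = true;
    atoms.push_back(v);
    std::string save = str;
    str += g.btok[last][k] + g.atok[v];
    collect_legs(g, centre, max_len, atoms, str, used, legs);
    str = save;
    atoms.pop_back();
    used[v] = false;
  }
}

static void star_combos(const Graph& g, int centre,
                        const std::vector<Leg>& legs, int max_bonds,
                        size_t start, std::vector<const Leg*>& chosen,
                        int bonds_used, std::vector<bool>& occupied,
                        std::set<uint32_t>& bits) {
  if (chosen.size() >= 3) {
    std::vector<std::string> ss;
    for (const Leg* l : chosen) ss.push_back(l->str);
    std::sort(ss.begin(), ss.end());
    std::string s = "T|" + g.atok[centre] + "(";
    for (size_t k = 0; k < ss.size(); ++k) s += (k ? "," : "") + ss[k];
    s += ")";
    bits.insert(fnv1a(s));
  }
  for (size_t k = start; k < legs.size(); ++k) {
    int nb = bonds_used + (int)legs[k].atoms.size();
    if (nb > max_bonds) continue;
    bool clash = false;
    for (int a : legs[k].atoms) if (occupied[a]) { clash = true; break; }
    if (clash) continue;
    for (int a : legs[k].atoms) occupied[a] = true;
    chosen.push_back(&legs[k]);
    star_combos(g, centre, legs, max_bonds, k + 1, chosen, nb, occupied, bits);
    chosen.pop_back();
    for (int a : legs[k].atoms) occupied[a] = false;
  }
}

// [[Rcpp::export]]
NumericVector cpp_dendritic_bits(CharacterVector atom_tokens,
                                 IntegerVector bond_i, IntegerVector bond_j,
                                 CharacterVector bond_tokens,
                                 int max_bonds) {
  Graph g = build_graph(atom_tokens, bond_i, bond_j, bond_tokens);
  std::set<uint32_t> bits;
  // single atoms (0-bond fragments)
  for (int a = 0; a < g.n; ++a) bits.insert(fnv1a("A|" + g.atok[a]));
  // simple paths
  for (int a = 0; a < g.n; ++a) {
    std::vector<int> atoms{a};
    std::vector<std::string> bonds;
    std::vector<bool> used(g.n, false);
    used[a] = true;
    enumerate_paths(g, max_bonds, atoms, bonds, used, bits);
  }
  // single-branch trees: >= 3 vertex-disjoint legs from one centre
  for (int c = 0; c < g.n; ++c) {
    if ((int)g.nbr[c].size() < 3) continue;
    std::vector<Leg> legs;
    std::vector<int> atoms;
    std::string str;
    std::vector<bool> used(g.n, false);
    collect_legs(g, c, max_bonds - 2, atoms, str, used, legs);
    std::vector<const Leg*> chosen;
    std::vector<bool> occupied(g.n, false);
    star_combos(g, c, legs, max_bonds, 0, chosen, 0, occupied, bits);
  }
  return set_to_bits(bits);
}

// MOLPRINT2D: one bit per heavy atom, encoding the centre's atom type and
// the sorted multiset of (graph distance in {1,2}, atom type) of its
// neighbours.  Atom tokens are SYBYL-style types supplied from R.
// [[Rcpp::export]]
NumericVector cpp_molprint_bits(CharacterVector atom_tokens,
                                IntegerVector bond_i, IntegerVector bond_j,
                                CharacterVector bond_tokens) {
  Graph g = build_graph(atom_tokens, bond_i, bond_j, bond_tokens);
  std::set<uint32_t> bits;
  for (int a = 0; a < g.n; ++a) {
    std::vector<int> dist(g.n, -1);
    dist[a] = 0;
    std::vector<int> q{a};
    for (size_t qi = 0; qi < q.size(); ++qi) {
      int u = q[qi];
      if (dist[u] >= 2) continue;
      for (int v : g.nbr[u])
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q.push_back(v); }
    }
    std::vector<std::string> env;
    for (int v = 0; v < g.n; ++v)
      if (dist[v] == 1 || dist[v] == 2)
        env.push_back(std::to_string(dist[v]) + ":" + g.atok[v]);
    std::sort(env.begin(), env.end());
    std::string s = "M|" + g.atok[a] + ";";
    for (size_t k = 0; k < env.size(); ++k) s += (k ? "," : "") + env[k];
    bits.insert(fnv1a(s));
  }
  return set_to_bits(bits);
}

// Tanimoto similarity between lists of sorted bit vectors: returns the
// |A|x|B| matrix of |intersection| / |union| with the empty-vs-empty
// convention fixed at 0.
// [[Rcpp::export]]
NumericMatrix cpp_tanimoto_matrix(List a, List b) {
  int na = a.size(), nb = b.size();
  std::vector<std::vector<double>> av(na), bv(nb);
  for (int i = 0; i < na; ++i) av[i] = as<std::vector<double>>(a[i]);
  for (int j = 0; j < nb; ++j) bv[j] = as<std::vector<double>>(b[j]);
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      const auto& x = av[i];
      const auto& y = bv[j];
      size_t p = 0, q = 0, inter = 0;
      while (p < x.size() && q < y.size()) {
        if (x[p] < y[q]) ++p;
        else if (x[p] > y[q]) ++q;
        else { ++inter; ++p; ++q; }
      }
      size_t uni = x.size() + y.size() - inter;
      out(i, j) = uni == 0 ? 0.0 : static_cast<double>(inter) / uni;
    }
  }
  return out;
}
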
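// Monte-Carlo engines for network-based enrichment.
//
// Both nulls spend their time computing connected-component sizes of small
// induced subgraphs inside a tight iteration loop, and the structure null
// additionally performs k*|I| edge-swap attempts per iteration; these loops
// live here.  All randomness comes from R's RNG (R_unif_index), so results
// are reproducible through set.seed().

#include <Rcpp.h>
#include <Rmath.h>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Compare two non-increasing component-size sequences, zero-padding the
// shorter one; returns -1 / 0 / 1 for a < b / a == b / a > b.
static int cmp_cs(const std::vector<int>& a, const std::vector<int>& b) {
    const size_t n = std::max(a.size(), b.size());
    for (size_t i = 0; i < n; ++i) {
        const int ai = i < a.size() ? a[i] : 0;
        const int bi = i < b.size() ? b[i] : 0;
        if (ai != bi) return ai < bi ? -1 : 1;
    }
    return 0;
}

struct UnionFind {
    std::vector<int> parent, csize;
    explicit UnionFind(int n) : parent(n, 0), csize(n, 0) {}
    void reset(const std::vector<int>& nodes) {
        for (int v : nodes) { parent[v] = v; csize[v] = 1; }
    }
    int find(int v) {
        while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
        return v;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (csize[a] < csize[b]) std::swap(a, b);
        parent[b] = a;
        csize[a] += csize[b];
    }
};

static inline long long edge_key(int a, int b, int n) {
    if (a > b) std::swap(a, b);
    return static_cast<long long>(a) * n + b;
}

// Degree-preserving rewiring: `attempts` double-edge-swap attempts.  Each
// attempt draws two distinct edges and one of the two possible endpoint
// exchanges uniformly; attempts that would create a self-loop or a duplicate
// edge leave the graph unchanged but are still consumed.
static void swap_randomize(std::vector<std::pair<int, int>>& ed,
                           std::unordered_set<long long>& eset,
                           int n, double attempts) {
    const int m = static_cast<int>(ed.size());
    if (m < 2) return;
    for (double t = 0; t < attempts; t += 1.0) {
        const int i = static_cast<int>(R_unif_index(m));
        int j = static_cast<int>(R_unif_index(m));
        while (j == i) j = static_cast<int>(R_unif_index(m));
        const int a = ed[i].first, b = ed[i].second;
        int c = ed[j].first, d = ed[j].second;
        if (R_unif_index(2.0) == 1.0) std::swap(c, d);
        // proposed replacement edges {a,c} and {b,d}
        if (a == c || b == d) continue;  // would create a self-loop
        const long long k1 = edge_key(a, c, n), k2 = edge_key(b, d, n);
        if (k1 == k2) continue;
        if (eset.count(k1) || eset.count(k2)) continue;  // would duplicate
        eset.erase(edge_key(a, b, n));
        eset.erase(edge_key(ed[j].first, ed[j].second, n));
        eset.insert(k1);
        eset.insert(k2);
        ed[i] = std::make_pair(a, c);
        ed[j] = std::make_pair(b, d);
    }
}

// Gather the non-increasing component-size sequence of the members of `nodes`
// after unions; `seen` must be all-zero on entry and is restored on exit.
static void gather_cs(UnionFind& uf, const std::vector<int>& nodes,
                      std::vector<char>& seen, std::vector<int>& cs) {
    cs.clear();
    for (int v : nodes) {
        const int r = uf.find(v);
        if (!seen[r]) { seen[r] = 1; cs.push_back(uf.csize[r]); }
    }
    for (int v : nodes) seen[uf.find(v)] = 0;
    std::sort(cs.begin(), cs.end(), std::greater<int>());
}

// Function-randomization null: draw u_f nodes without replacement from the
// universe, induce the interesting network on the draw, and count draws whose
// component-size sequence is >= the observed one.
// h_edges: 0-based edge matrix of the interesting network (universe indices);
// h_member: universe-length membership mask of the interesting node set.
// [[Rcpp::export]]
int cpp_function_null_count(int n_universe, IntegerMatrix h_edges,
                            LogicalVector h_member, int u_f,
                            IntegerVector obs_cs, int iterations) {
    const int n = n_universe, m = h_edges.nrow();
    const std::vector<int> obs(obs_cs.begin(), obs_cs.end());
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    std::vector<char> sel(n, 0), seen(n, 0);
    UnionFind uf(n);
    std::vector<int> chosen, hchosen, cs;
    chosen.reserve(u_f);
    hchosen.reserve(u_f);
    cs.reserve(u_f);
    int count = 0;
    for (int it = 0; it < iterations; ++it) {
        chosen.clear();
        hchosen.clear();
        for (int i = 0; i < u_f; ++i) {
            const int j = i + static_cast<int>(R_unif_index(n - i));
            std::swap(pool[i], pool[j]);
            const int v = pool[i];
            chosen.push_back(v);
            sel[v] = 1;
            if (h_member[v]) hchosen.push_back(v);
        }
        uf.reset(hchosen);
        for (int e = 0; e < m; ++e) {
            const int a = h_edges(e, 0), b = h_edges(e, 1);
            if (sel[a] && sel[b]) uf.unite(a, b);
        }
        gather_cs(uf, hchosen, seen, cs);
        if (cmp_cs(cs, obs) >= 0) ++count;
        for (int v : chosen) sel[v] = 0;
        if ((it & 8191) == 0) Rcpp::checkUserInterrupt();
    }
    return count;
}

// One degree-preserving randomization of an edge list (0-based, n nodes),
// floor(k*m) swap attempts.
// [[Rcpp::export]]
IntegerMatrix cpp_randomize_edges(IntegerMatrix edges, int n, double k) {
    const int m = edges.nrow();
    std::vector<std::pair<int, int>> ed(m);
    std::unordered_set<long long> eset;
    for (int e = 0; e < m; ++e) {
        ed[e] = std::make_pair(edges(e, 0), edges(e, 1));
        eset.insert(edge_key(ed[e].first, ed[e].second, n));
    }
    swap_randomize(ed, eset, n, std::floor(k * m));
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
        out(e, 0) = ed[e].first;
        out(e, 1) = ed[e].second;
    }
    return out;
}

// Structure-randomization null: at each iteration rewire the universal
// network afresh and, for every term, compare the component-size sequence of
// the subgraph induced on that term's member nodes against its observed
// sequence.  One shared sequence of randomized networks serves all terms.
// members: list of 0-based index vectors (term genes inside the interesting
// node set); obs_list: matching observed component-size sequences.
// [[Rcpp::export]]
IntegerVector cpp_structure_null_counts(IntegerMatrix edges, int n, double k,
                                        int iterations, List members,
                                        List obs_list) {
    const int m = edges.nrow(), nt = members.size();
    std::vector<std::pair<int, int>> base(m);
    std::unordered_set<long long> base_set;
    for (int e = 0; e < m; ++e) {
        base[e] = std::make_pair(edges(e, 0), edges(e, 1));
        base_set.insert(edge_key(base[e].first, base[e].second, n));
    }
    std::vector<std::vector<int>> mem(nt), obs(nt);
    std::vector<std::vector<char>> mask(nt, std::vector<char>(n, 0));
    for (int t = 0; t < nt; ++t) {
        mem[t] = as<std::vector<int>>(members[t]);
        obs[t] = as<std::vector<int>>(obs_list[t]);
        for (int v : mem[t]) mask[t][v] = 1;
    }
    IntegerVector counts(nt);
    UnionFind uf(n);
    std::vector<char> seen(n, 0);
    std::vector<int> cs;
    const double attempts = std::floor(k * m);
    std::vector<std::pair<int, int>> ed;
    std::unordered_set<long long> eset;
    for (int it = 0; it < iterations; ++it) {
        ed = base;
        eset = base_set;
        swap_randomize(ed, eset, n, attempts);
        for (int t = 0; t < nt; ++t) {
            uf.reset(mem[t]);
            const std::vector<char>& mk = mask[t];
            for (int e = 0; e < m; ++e) {
                const int a = ed[e].first, b = ed[e].second;
                if (mk[a] && mk[b]) uf.unite(a, b);
            }
            gather_cs(uf, mem[t], seen, cs);
            if (cmp_cs(cs, obs[t]) >= 0) ++counts[t];
        }
        if ((it & 255) == 0) Rcpp::checkUserInterrupt();
    }
    return counts;
}
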
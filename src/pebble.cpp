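// (6,6) body-bar pebble game.
//
// Each node (rigid body) carries 6 pebbles (its free degrees of freedom).
// A bar (edge) is independent iff 7 pebbles can be gathered on its two
// endpoints before covering it; covering takes one pebble from the tail
// and directs the edge away from it.  Pebble searches follow directed
// covered edges; retrieving a pebble reverses the search path.  All
// searches use sorted (ascending node id) neighbour order so results are
// bit-stable for a fixed edge insertion order.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

const int K = 6;  // pebbles per body (3D rigid body DOF)
const int L = 6;  // sparsity offset: accept edge iff L+1 pebbles on pair

struct PebbleGame {
    int n;
    std::vector<int> peb;
    // adj[u*n + v] = number of covered edges directed u -> v
    std::vector<int> adj;
    int accepted;

    explicit PebbleGame(int n_) : n(n_), peb(n_, K), adj((size_t)n_ * n_, 0),
                                  accepted(0) {}

    // Depth-first search from `start` along directed covered edges for a
    // node (not in {a,b}) holding a free pebble.  On success the pebble is
    // moved to `start` by reversing the path.  Deterministic: neighbours
    // visited in ascending id order.
    bool findPebble(int start, int a, int b) {
        std::vector<int> parent(n, -2);
        parent[start] = -1;
        std::vector<int> stack;
        stack.push_back(start);
        while (!stack.empty()) {
            int u = stack.back();
            stack.pop_back();
            for (int v = n - 1; v >= 0; --v) {  // pushed desc => popped asc
                if (adj[(size_t)u * n + v] > 0 && parent[v] == -2) {
                    parent[v] = u;
                    if (v != a && v != b && peb[v] > 0) {
                        peb[v]--;
                        int x = v;
                        while (parent[x] != -1) {
                            int p = parent[x];
                            adj[(size_t)p * n + x]--;
                            adj[(size_t)x * n + p]++;
                            x = p;
                        }
                        peb[start]++;
                        return true;
                    }
                    stack.push_back(v);
                }
            }
        }
        return false;
    }

    // Gather pebbles on {u,v} until `target` are present or none reachable.
    int collect(int u, int v, int target) {
        while (peb[u] + peb[v] < target) {
            if (findPebble(u, u, v)) continue;
            if (findPebble(v, u, v)) continue;
            break;
        }
        return peb[u] + peb[v];
    }

    // Try to insert one bar between u and v; true iff independent.
    bool insertEdge(int u, int v) {
        if (collect(u, v, L + 1) >= L + 1) {
            int tail = (peb[u] > 0) ? u : v;
            int head = (tail == u) ? v : u;
            adj[(size_t)tail * n + head]++;
            peb[tail]--;
            accepted++;
            return true;
        }
        return false;
    }

    // Relative DOF remaining between u and v: max pebbles collectible on
    // the pair minus 6, clamped to [0, 6].
    int dofBetween(int u, int v) {
        int got = collect(u, v, 2 * K + 1);  // unreachable target => maxes out
        int dof = got - K;
        if (dof < 0) dof = 0;
        if (dof > K) dof = K;
        return dof;
    }
};

struct UnionFind {
    std::vector<int> up;
    explicit UnionFind(int n) : up(n) {
        for (int i = 0; i < n; ++i) up[i] = i;
    }
    int find(int x) {
        while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; }
        return x;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (a < b) up[b] = a; else up[a] = b;  // keep smallest id as root
    }
};

void checkEdges(int n, const IntegerMatrix& edges) {
    for (int i = 0; i < edges.nrow(); ++i) {
        int u = edges(i, 0), v = edges(i, 1);
        if (u < 1 || u > n || v < 1 || v > n)
            stop("edge endpoint out of range");
        if (u == v) stop("invalid graph: self-loop");
    }
}

}  // namespace

// Run the pebble game over `edges` (m x 2, 1-based node ids, one row per
// bar, processed in row order).  Returns acceptance per bar, final pebble
// counts, total free DOF, and the rigid-cluster label (1-based, smallest
// member id) of every node.  Clusters are derived from the final pebble
// state: two adjacent bodies belong to one cluster iff their relative DOF
// is 0; for body-bar frameworks rigid components partition the bodies and
// are internally connected, so union-find over adjacent zero-DOF pairs
// yields the full decomposition.
// [[Rcpp::export]]
List cpp_pebble_game(int n, IntegerMatrix edges) {
    if (n < 1) stop("need at least one node");
    checkEdges(n, edges);
    PebbleGame pg(n);
    int m = edges.nrow();
    LogicalVector acc(m);
    for (int i = 0; i < m; ++i)
        acc[i] = pg.insertEdge(edges(i, 0) - 1, edges(i, 1) - 1);

    // distinct adjacent pairs, ascending
    std::vector<std::pair<int,int> > pairs;
    for (int i = 0; i < m; ++i) {
        int u = edges(i, 0) - 1, v = edges(i, 1) - 1;
        if (u > v) std::swap(u, v);
        pairs.push_back(std::make_pair(u, v));
    }
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());

    UnionFind uf(n);
    for (size_t i = 0; i < pairs.size(); ++i)
        if (pg.dofBetween(pairs[i].first, pairs[i].second) == 0)
            uf.unite(pairs[i].first, pairs[i].second);

    IntegerVector labels(n);
    for (int i = 0; i < n; ++i) labels[i] = uf.find(i) + 1;

    IntegerVector pebbles(n);
    for (int i = 0; i < n; ++i) pebbles[i] = pg.peb[i];

    return List::create(
        _["accepted"] = acc,
        _["pebbles"] = pebbles,
        _["totalFreeDof"] = K * n - pg.accepted,
        _["clusterLabels"] = labels);
}

// Relative DOF between nodes u and v (1-based) after playing the full game.
// [[Rcpp::export]]
int cpp_pebble_dof(int n, IntegerMatrix edges, int u, int v) {
    if (n < 1) stop("need at least one node");
    if (u < 1 || u > n || v < 1 || v > n) stop("unknown node");
    checkEdges(n, edges);
    PebbleGame pg(n);
    for (int i = 0; i < edges.nrow(); ++i)
        pg.insertEdge(edges(i, 0) - 1, edges(i, 1) - 1);
    if (u == v) return 0;
    return pg.dofBetween(u - 1, v - 1);
}
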
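// FMD-index core: SA-IS suffix array construction, BWT with checkpointed
// rank tables, bidirectional bi-interval extension and the Ping-Pong search.
//
// Symbol classes used throughout:
//   0 = sentinel (string separators; never matched by queries)
//   1 = A, 2 = C, 3 = G, 4 = T        complement(a) = 5 - a
//
// Two index layouts share the same machinery:
//   * both-strands mode: one BWT over {s_1, rc(s_1), ..., s_k, rc(s_k)};
//     the bi-interval [i, j, l] pairs the Q-interval with the rc(Q)-interval
//     in the same generalized suffix array (the FMD-index construction).
//   * single-strand mode: BWT over {s_1, ..., s_k} plus a second BWT over
//     the reversed strings; [i, j, l] pairs the Q-interval with the
//     reverse(Q)-interval of the second array (a plain bidirectional
//     FM-index, used where reverse-complement membership must be excluded).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

static const int CKPT = 64; // rank checkpoint spacing (positions)

// ---------------------------------------------------------------------------
// SA-IS: linear-time suffix array over an integer alphabet [0, K).
// Requires s[n-1] to be the unique lexicographically smallest symbol.
// ---------------------------------------------------------------------------
static void sais(const int32_t* s, int32_t* SA, int32_t n, int32_t K)
{
    if (n == 1) { SA[0] = 0; return; }

    std::vector<bool> stype(n);
    stype[n - 1] = true;
    for (int32_t i = n - 2; i >= 0; --i)
        stype[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && stype[i + 1]);
    auto is_lms = [&](int32_t i) { return i > 0 && stype[i] && !stype[i - 1]; };

    std::vector<int32_t> bkt(K);
    auto bucket_bounds = [&](bool end) {
        std::fill(bkt.begin(), bkt.end(), 0);
        for (int32_t i = 0; i < n; ++i) bkt[s[i]]++;
        int32_t sum = 0;
        for (int32_t k = 0; k < K; ++k) {
            sum += bkt[k];
            bkt[k] = end ? sum : sum - bkt[k];
        }
    };
    auto induce = [&]() {
        bucket_bounds(false);
        for (int32_t i = 0; i < n; ++i) {
            int32_t j = SA[i] - 1;
            if (SA[i] > 0 && !stype[j]) SA[bkt[s[j]]++] = j;
        }
        bucket_bounds(true);
        for (int32_t i = n - 1; i >= 0; --i) {
            int32_t j = SA[i] - 1;
            if (SA[i] > 0 && stype[j]) SA[--bkt[s[j]]] = j;
        }
    };

    // Stage 1: approximately sort LMS suffixes by their first symbol, induce.
    std::fill(SA, SA + n, -1);
    bucket_bounds(true);
    for (int32_t i = 1; i < n; ++i)
        if (is_lms(i)) SA[--bkt[s[i]]] = i;
    induce();

    // Collect LMS positions in induced order; name their LMS substrings.
    int32_t n1 = 0;
    for (int32_t i = 0; i < n; ++i)
        if (SA[i] > 0 && is_lms(SA[i])) SA[n1++] = SA[i];
    for (int32_t i = n1; i < n; ++i) SA[i] = -1;

    int32_t name = 0, prev = -1;
    for (int32_t i = 0; i < n1; ++i) {
        int32_t pos = SA[i];
        bool diff = false;
        if (prev < 0) diff = true;
        else {
            for (int32_t d = 0;; ++d) {
                if (s[pos + d] != s[prev + d]) { diff = true; break; }
                if (d > 0) {
                    bool l1 = is_lms(pos + d), l2 = is_lms(prev + d);
                    if (l1 != l2) { diff = true; break; }
                    if (l1) break; // both reached the next LMS: identical
                }
            }
        }
        if (diff) { ++name; prev = pos; }
        SA[n1 + pos / 2] = name - 1;
    }
    for (int32_t i = n - 1, j = n - 1; i >= n1; --i)
        if (SA[i] >= 0) SA[j--] = SA[i];

    // Stage 2: sort the reduced problem (names in text order), then induce.
    int32_t* s1 = SA + n - n1;
    if (name < n1) {
        sais(s1, SA, n1, name);
    } else {
        for (int32_t i = 0; i < n1; ++i) SA[s1[i]] = i;
    }
    {
        int32_t j = 0;
        for (int32_t i = 1; i < n; ++i)
            if (is_lms(i)) s1[j++] = i;
        for (int32_t i = 0; i < n1; ++i) SA[i] = s1[SA[i]];
    }
    for (int32_t i = n1; i < n; ++i) SA[i] = -1;
    bucket_bounds(true);
    for (int32_t i = n1 - 1; i >= 0; --i) {
        int32_t j = SA[i];
        SA[i] = -1;
        SA[--bkt[s[j]]] = j;
    }
    induce();
}

// ---------------------------------------------------------------------------
// Text assembly and BWT
// ---------------------------------------------------------------------------

static inline int enc_base(char c)
{
    switch (c) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 3;
    case 'T': return 4;
    default: return -1;
    }
}

// Concatenate documents with separator symbol 1 after each; the very last
// separator becomes 0, the unique smallest terminator SA-IS requires.
// (All separators collapse to symbol class 0 in the stored BWT.)
static std::vector<int32_t> concat_docs(const std::vector<std::string>& docs)
{
    size_t total = 0;
    for (const auto& d : docs) total += d.size() + 1;
    if (total > (size_t)INT32_MAX - 2)
        stop("collection too large to index (2^31 symbol limit)");
    std::vector<int32_t> text;
    text.reserve(total);
    for (const auto& d : docs) {
        for (char c : d) {
            int b = enc_base(c);
            if (b < 0) stop("invalid symbol in sequence (expected A/C/G/T)");
            text.push_back(b + 1); // shift: separators get 0/1, bases 2..5
        }
        text.push_back(1);
    }
    text.back() = 0;
    return text;
}

static RawVector bwt_of(const std::vector<int32_t>& text)
{
    int32_t n = (int32_t)text.size();
    std::vector<int32_t> SA(n);
    sais(text.data(), SA.data(), n, 6);
    RawVector bwt(n);
    for (int32_t i = 0; i < n; ++i) {
        int32_t v = SA[i] > 0 ? text[SA[i] - 1] : text[n - 1];
        bwt[i] = (Rbyte)(v <= 1 ? 0 : v - 1); // collapse separators, unshift
    }
    return bwt;
}

// Checkpointed occurrence table: counts of classes 1..4 before each
// checkpoint position (4 entries per checkpoint, positions 0, CKPT, ...).
// [[Rcpp::export]]
IntegerVector cpp_occ_build(RawVector bwt)
{
    int32_t n = bwt.size();
    int32_t nck = n / CKPT + 1;
    IntegerVector occ(4 * nck);
    int32_t cnt[5] = {0, 0, 0, 0, 0};
    for (int32_t i = 0; i < n; ++i) {
        if (i % CKPT == 0) {
            int32_t k = i / CKPT;
            for (int c = 1; c <= 4; ++c) occ[4 * k + c - 1] = cnt[c];
        }
        cnt[bwt[i]]++;
    }
    int32_t k = n / CKPT;
    if (k * CKPT == n) // grid point at n itself is never reached in the loop
        for (int c = 1; c <= 4; ++c) occ[4 * k + c - 1] = cnt[c];
    return occ;
}

// [[Rcpp::export]]
IntegerVector cpp_symbol_counts(RawVector bwt)
{
    IntegerVector cnt(5);
    int32_t n = bwt.size();
    for (int32_t i = 0; i < n; ++i) cnt[bwt[i]]++;
    return cnt;
}

// ---------------------------------------------------------------------------
// Rank queries and bi-interval extension
// ---------------------------------------------------------------------------

struct View {
    const Rbyte* bwt;
    const int* occ;
    const int* C; // C[c] = number of symbols of class < c, c in 0..5
    int32_t n;
};

static inline int32_t rank1(const View& v, int c, int32_t pos)
{
    int32_t k = pos / CKPT;
    int32_t r = v.occ[4 * k + c - 1];
    for (int32_t p = k * CKPT; p < pos; ++p) r += (v.bwt[p] == c);
    return r;
}

static inline void counts_in(const View& v, int32_t from, int32_t width,
                             int32_t cnt[5])
{
    int32_t lo[5] = {0, 0, 0, 0, 0}, hi[5] = {0, 0, 0, 0, 0};
    for (int c = 1; c <= 4; ++c) {
        lo[c] = rank1(v, c, from);
        hi[c] = rank1(v, c, from + width);
    }
    cnt[0] = width;
    for (int c = 1; c <= 4; ++c) {
        cnt[c] = hi[c] - lo[c];
        cnt[0] -= cnt[c];
    }
}

struct BI { int32_t i, j, l; };

// sigma+Q from the Q-interval, both-strands (FMD) layout: the paired
// interval is rc(Q); appending comp(sigma) to rc(Q) shifts j past the
// sentinel block and every extension group lexicographically above sigma.
static BI back_both(const View& v, BI b, int a)
{
    int32_t cnt[5];
    counts_in(v, b.i, b.l, cnt);
    BI r;
    r.i = v.C[a] + rank1(v, a, b.i);
    r.l = cnt[a];
    r.j = b.j + cnt[0];
    for (int c = a + 1; c <= 4; ++c) r.j += cnt[c];
    return r;
}

// sigma+Q, single-strand layout: the paired interval is reverse(Q) in the
// reversed-text array; appending sigma there shifts j past the sentinel
// block and the groups lexicographically below sigma.
static BI back_single(const View& v, BI b, int a)
{
    int32_t cnt[5];
    counts_in(v, b.i, b.l, cnt);
    BI r;
    r.i = v.C[a] + rank1(v, a, b.i);
    r.l = cnt[a];
    r.j = b.j + cnt[0];
    for (int c = 1; c < a; ++c) r.j += cnt[c];
    return r;
}

struct Index {
    View fwd;     // BWT of the documents
    View rev;     // BWT of the reversed documents (single mode only)
    bool both;
    long* n_ext;  // instrumentation: extension operation counter
};

static BI ext_backward(const Index& x, BI b, int a)
{
    if (x.n_ext) ++*x.n_ext;
    return x.both ? back_both(x.fwd, b, a) : back_single(x.fwd, b, a);
}

static BI ext_forward(const Index& x, BI b, int a)
{
    if (x.n_ext) ++*x.n_ext;
    BI s{b.j, b.i, b.l}, r;
    r = x.both ? back_both(x.fwd, s, 5 - a) : back_single(x.rev, s, a);
    return BI{r.j, r.i, r.l};
}

static BI bi_init(const Index& x, int a)
{
    const int* C = x.fwd.C;
    int32_t jj = x.both ? C[5 - a] : C[a];
    return BI{C[a], jj, C[a + 1] - C[a]};
}

static Index open_index(const List& idx, long* counter)
{
    Index x;
    RawVector bwt = idx["bwt"];
    IntegerVector occ = idx["occ"];
    IntegerVector C = idx["C"];
    x.fwd = View{bwt.begin(), occ.begin(), C.begin(), (int32_t)bwt.size()};
    std::string mode = as<std::string>(idx["strand_mode"]);
    x.both = (mode == "both");
    if (!x.both) {
        RawVector rbwt = idx["rbwt"];
        IntegerVector rocc = idx["rocc"];
        x.rev = View{rbwt.begin(), rocc.begin(), C.begin(),
                     (int32_t)rbwt.size()};
    }
    x.n_ext = counter;
    return x;
}

static std::vector<uint8_t> enc_query(const std::string& q)
{
    if (q.empty()) stop("empty query");
    std::vector<uint8_t> t(q.size());
    for (size_t i = 0; i < q.size(); ++i) {
        int b = enc_base(q[i]);
        if (b < 0) stop("invalid symbol in query (expected A/C/G/T)");
        t[i] = (uint8_t)b;
    }
    return t;
}

// ---------------------------------------------------------------------------
// Exported index construction and primitive queries
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_fmd(std::vector<std::string> seqs, bool both)
{
    if (seqs.empty()) stop("nothing to index");
    std::vector<std::string> docs;
    docs.reserve(seqs.size() * (both ? 2 : 1));
    for (const auto& s : seqs) {
        if (s.empty()) stop("empty sequence cannot be indexed");
        docs.push_back(s);
        if (both) {
            std::string rc(s.size(), 'N');
            for (size_t i = 0; i < s.size(); ++i) {
                char c = s[s.size() - 1 - i];
                rc[i] = c == 'A' ? 'T' : c == 'C' ? 'G' : c == 'G' ? 'C' : 'A';
            }
            docs.push_back(rc);
        }
    }
    std::vector<int32_t> text = concat_docs(docs);
    RawVector bwt = bwt_of(text);
    List out = List::create(
        _["bwt"] = bwt,
        _["occ"] = cpp_occ_build(bwt),
        _["strand_mode"] = both ? "both" : "single",
        _["n_sequences"] = (int)seqs.size());
    if (!both) {
        std::vector<std::string> rdocs(docs);
        for (auto& d : rdocs) std::reverse(d.begin(), d.end());
        std::vector<int32_t> rtext = concat_docs(rdocs);
        RawVector rbwt = bwt_of(rtext);
        out["rbwt"] = rbwt;
        out["rocc"] = cpp_occ_build(rbwt);
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_init(List idx, int sym)
{
    Index x = open_index(idx, nullptr);
    BI b = bi_init(x, sym);
    return IntegerVector::create(b.i, b.j, b.l);
}

// [[Rcpp::export]]
IntegerVector cpp_extend(List idx, IntegerVector bi, int sym, bool forward)
{
    Index x = open_index(idx, nullptr);
    BI b{bi[0], bi[1], bi[2]};
    BI r = forward ? ext_forward(x, b, sym) : ext_backward(x, b, sym);
    return IntegerVector::create(r.i, r.j, r.l);
}

// Width of the Q-interval after chaining backward extensions over q
// (right to left); the substring occurrence count of q in the index.
// [[Rcpp::export]]
int cpp_match_width(List idx, std::string q)
{
    Index x = open_index(idx, nullptr);
    std::vector<uint8_t> t = enc_query(q);
    int m = (int)t.size();
    BI b = bi_init(x, t[m - 1]);
    for (int k = m - 2; k >= 0 && b.l > 0; --k)
        b = ext_backward(x, b, t[k]);
    return b.l;
}

// ---------------------------------------------------------------------------
// Ping-Pong search
// ---------------------------------------------------------------------------

// Emits, for every viable start position of t, the shortest substring of t
// starting there that does not occur in the index.  Exact mode restores the
// pre-failure interval after each emission so consecutive solutions may
// overlap; relaxed mode restarts one position left of the last emission,
// which makes emissions pairwise disjoint and the scan linear.
// Returned begin/end are 0-based INCLUSIVE (converted to half-open in R).
// [[Rcpp::export]]
List cpp_pingpong(List idx, std::string target, bool relaxed)
{
    long n_ext = 0;
    Index x = open_index(idx, &n_ext);
    std::vector<uint8_t> t = enc_query(target);
    int32_t n = (int32_t)t.size();
    std::vector<int32_t> outb, oute;

    int32_t b = n - 1;
    BI bi = bi_init(x, t[b]);
    while (true) {
        // Step 1: backward extension until the interval empties (or b = 0)
        while (bi.l != 0 && b > 0) {
            --b;
            bi = ext_backward(x, bi, t[b]);
        }
        if (bi.l != 0 && b == 0) break; // t[0..e] occurs: nothing left of it

        int32_t e = b;
        bi = bi_init(x, t[e]);
        if (bi.l == 0) {
            // t[b] itself is absent: the length-1 string is the solution here
            outb.push_back(b);
            oute.push_back(b);
            if (b == 0) break;
            --b;
            bi = bi_init(x, t[b]);
            continue;
        }

        // Step 2: forward extension of the shortest absent prefix from b
        BI saved = bi;
        while (bi.l != 0) {
            saved = bi;
            ++e;
            if (e >= n)
                stop("internal error: forward extension ran past target end");
            bi = ext_forward(x, bi, t[e]);
        }
        outb.push_back(b);
        oute.push_back(e);

        if (relaxed) {
            if (b == 0) break;
            --b;
            bi = bi_init(x, t[b]);
        } else {
            bi = saved; // interval of t[b..e-1]; resume backward from b
        }
    }

    return List::create(_["begin"] = wrap(outb), _["end"] = wrap(oute),
                        _["n_extensions"] = (double)n_ext);
}
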
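#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Prefix-spelling enumeration of simple motifs under the Hamming model.
// Candidate consensus words are grown one base at a time; each live
// prefix carries the list of sequence windows that match it with at most
// maxErr mismatches so far. A prefix is abandoned as soon as the number
// of distinct sequences among its windows drops below the quorum
// threshold (support can only shrink under extension) and, in frequent
// mode, as soon as no window matches it exactly. Windows are visited in
// (sequence, position) order and filtering preserves that order, so
// emitted occurrence lists are sorted without an explicit sort.

namespace {

struct Occ {
    int seq;
    int pos;            // 0-based window start
    unsigned char mism; // mismatches accumulated over the spelled prefix
};

struct SpellWalk {
    const std::vector<std::vector<unsigned char> >& seqs;
    int len, maxErr, qmin;
    bool requireExact;
    // one 4-way child buffer per depth: a single pass over the parent's
    // occurrences partitions them among the four extension letters
    std::vector<std::vector<std::vector<Occ> > > buf;
    std::string word;
    std::vector<std::string> motifs;
    std::vector<std::vector<Occ> > motifOccs;

    SpellWalk(const std::vector<std::vector<unsigned char> >& s,
            int len_, int maxErr_, int qmin_, bool requireExact_)
        : seqs(s), len(len_), maxErr(maxErr_), qmin(qmin_),
          requireExact(requireExact_),
          buf(len_, std::vector<std::vector<Occ> >(4)),
          word(len_, 'A') {}

    static int supportOf(const std::vector<Occ>& occs) {
        int n = 0, last = -1;
        for (size_t i = 0; i < occs.size(); ++i)
            if (occs[i].seq != last) { ++n; last = occs[i].seq; }
        return n;
    }

    static bool hasExact(const std::vector<Occ>& occs) {
        for (size_t i = 0; i < occs.size(); ++i)
            if (occs[i].mism == 0) return true;
        return false;
    }

    void run() {
        std::vector<Occ> root;
        for (size_t s = 0; s < seqs.size(); ++s) {
            int nwin = (int)seqs[s].size() - len + 1;
            for (int p = 0; p < nwin; ++p) {
                Occ o; o.seq = (int)s; o.pos = p; o.mism = 0;
                root.push_back(o);
            }
        }
        extend(0, root);
    }

    void extend(int depth, const std::vector<Occ>& cur) {
        if (supportOf(cur) < qmin) return;
        if (requireExact && !hasExact(cur)) return;
        if (depth == len) {
            motifs.push_back(word);
            motifOccs.push_back(cur);
            return;
        }
        std::vector<std::vector<Occ> >& ch = buf[depth];
        for (int a = 0; a < 4; ++a) ch[a].clear();
        for (size_t i = 0; i < cur.size(); ++i) {
            const Occ& o = cur[i];
            unsigned char c = seqs[o.seq][o.pos + depth];
            if (o.mism == (unsigned char)maxErr) {
                ch[c].push_back(o); // no budget left: matching letter only
            } else {
                for (unsigned char a = 0; a < 4; ++a) {
                    Occ x; x.seq = o.seq; x.pos = o.pos;
                    x.mism = o.mism + (a != c ? 1 : 0);
                    ch[a].push_back(x);
                }
            }
        }
        static const char bases[4] = {'A', 'C', 'G', 'T'};
        for (int a = 0; a < 4; ++a) {
            word[depth] = bases[a];
            extend(depth + 1, ch[a]);
        }
    }
};

std::vector<unsigned char> encode(const std::string& s) {
    std::vector<unsigned char> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': v[i] = 0; break;
        case 'C': v[i] = 1; break;
        case 'G': v[i] = 2; break;
        case 'T': v[i] = 3; break;
        default: stop("sequences must be over {A,C,G,T}");
        }
    }
    return v;
}

} // namespace

// [[Rcpp::export(name = ".spellMotifsCpp")]]
List spellMotifsCpp(CharacterVector sequences, int len, int maxErr,
                    int qmin, bool requireExact) {
    std::vector<std::vector<unsigned char> > seqs(sequences.size());
    for (int i = 0; i < sequences.size(); ++i)
        seqs[i] = encode(as<std::string>(sequences[i]));

    SpellWalk sp(seqs, len, maxErr, qmin, requireExact);
    sp.run();

    int n = (int)sp.motifs.size();
    CharacterVector consensus(n);
    List occurrences(n);
    IntegerVector support(n);
    for (int i = 0; i < n; ++i) {
        consensus[i] = sp.motifs[i];
        const std::vector<Occ>& occ = sp.motifOccs[i];
        IntegerMatrix m((int)occ.size(), 2);
        for (size_t j = 0; j < occ.size(); ++j) {
            m(j, 0) = occ[j].seq + 1; // 1-based
            m(j, 1) = occ[j].pos + 1;
        }
        colnames(m) = CharacterVector::create("seq", "start");
        occurrences[i] = m;
        support[i] = SpellWalk::supportOf(occ);
    }
    return List::create(_["consensus"] = consensus,
                        _["occurrences"] = occurrences,
                        _["support"] = support);
}
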
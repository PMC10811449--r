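# Name pools for the synthetic cohort generator. All names are synthetic
# draws from common-name lists; no real person data. None contain digits,
# special characters or the substring "TEST", so contamination counts stay
# exactly as planted.

.syn_surnames <- c(
  "ABBOTT", "ACOSTA", "ADLER", "AINSWORTH", "ALVAREZ", "ANDERSEN", "ARCHER",
  "ARMSTRONG", "ASHFORD", "ATKINSON", "BAILEY", "BALLARD", "BARLOW",
  "BARRERA", "BECKETT", "BELMONT", "BENSON", "BERGSTROM", "BLACKWOOD",
  "BOWMAN", "BRENNAN", "BRIGHTON", "CABRERA", "CALDWELL", "CAMPOS",
  "CARMICHAEL", "CARSON", "CASTELLANO", "CHAMBERS", "CHANDLER", "CLEMENT",
  "COLEMAN", "CORDOVA", "CRAWFORD", "CURRAN", "DALTON", "DELACRUZ",
  "DEMPSEY", "DONOVAN", "DRAPER", "DUFFY", "EASTWOOD", "ELDRIDGE",
  "ELLISON", "EMERSON", "ESCOBAR", "FAIRBANKS", "FARLEY", "FIGUEROA",
  "FINLEY", "FITZGERALD", "FLEMING", "FONTAINE", "FORSYTHE", "FRAZIER",
  "GALLAGHER", "GARRISON", "GIBSON", "GOLDMAN", "GRANGER", "GREENWOOD",
  "GRIFFITH", "GUSTAFSON", "HALVORSEN", "HAMMOND", "HARRELL", "HASTINGS",
  "HAWTHORNE", "HENDERSON", "HOLLAND", "HOLLOWAY", "HUBBARD", "INGRAM",
  "IVERSON", "JACOBSEN", "JARVIS", "JIMENEZ", "KEARNEY", "KELLERMAN",
  "KENDALL", "KIRKLAND", "KOWALSKI", "LAMBERT", "LANCASTER", "LARSEN",
  "LINDGREN", "LOCKHART", "MACDONALD", "MAGNUSSON", "MALDONADO", "MARLOWE",
  "MCALLISTER", "MERCADO", "MIDDLETON", "MONAHAN", "MONTGOMERY", "MORALES",
  "NAKAMURA", "NAVARRO", "NEWBERRY", "NICHOLSON", "NORWOOD", "OAKLEY",
  "OCONNOR", "ODONNELL", "OKAFOR", "OLIVEIRA", "PALMER", "PEMBERTON",
  "PENNINGTON", "PETROV", "PRESCOTT", "QUIGLEY", "QUINTERO", "RADCLIFFE",
  "RAMSEY", "REDMOND", "REYNOLDS", "RICHTER", "ROSARIO", "ROSSI",
  "SALINAS", "SANDOVAL", "SAWYER", "SCHNEIDER", "SHEPHERD", "SINCLAIR",
  "SOLOMON", "STANTON", "SULLIVAN", "TAKAHASHI", "THORNTON", "TILLMAN",
  "UNDERWOOD", "VALENTINE", "VASQUEZ", "VAUGHN", "WAINWRIGHT", "WALLACE",
  "WEBSTER", "WHITFIELD", "WINCHESTER", "WOODRUFF", "YAMAMOTO", "ZAVALA"
)

.syn_given <- c(
  "AARON", "ABIGAIL", "ADRIAN", "ALICE", "AMELIA", "ANDREW", "ANGELA",
  "ANTHONY", "AUDREY", "BARBARA", "BENJAMIN", "BEVERLY", "BRIAN",
  "CAROLINE", "CATHERINE", "CHARLES", "CLARA", "DANIEL", "DEBORAH",
  "DENNIS", "DIANA", "DOUGLAS", "EDWARD", "ELAINE", "ELEANOR", "ELIZABETH",
  "EMILY", "ERIC", "EVELYN", "FIONA", "FRANCES", "FREDERICK", "GEORGE",
  "GLORIA", "GORDON", "GRACE", "GREGORY", "HANNAH", "HAROLD", "HELEN",
  "HENRY", "HOWARD", "IRENE", "ISAAC", "JACQUELINE", "JAMES", "JANET",
  "JEFFREY", "JOANNE", "JONATHAN", "JOSEPHINE", "JUDITH", "JULIA",
  "KATHERINE", "KENNETH", "LAWRENCE", "LEONARD", "LILLIAN", "LOUISE",
  "LUCAS", "MARGARET", "MARIANNE", "MARTIN", "MATTHEW", "MIRIAM", "NANCY",
  "NATHAN", "NICHOLAS", "NORA", "OLIVER", "PAMELA", "PATRICIA", "PAULINE",
  "PETER", "PHILIP", "RACHEL", "RAYMOND", "REBECCA", "RICHARD", "ROBERT",
  "ROSEMARY", "RUSSELL", "RUTH", "SAMUEL", "SANDRA", "SHARON", "SIMON",
  "STANLEY", "SUSAN", "SYLVIA", "THEODORE", "THERESA", "TIMOTHY", "VALERIE",
  "VERONICA", "VICTOR", "VIRGINIA", "VIVIAN", "WALTER", "WESLEY", "YVONNE"
)

.syn_suffixes <- c("JR", "SR", "II", "III", "IV")
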